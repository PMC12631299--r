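mode_code,objective,wsm_l,wsm_m,wsm_u,wpm_l,wpm_m,wpm_u
F01,Delivery to Client,0.264,0.311,0.472,0.153,0.276,0.541
F01,Freight Cost,0.309,0.377,0.535,0.236,0.374,0.641
F02,Delivery to Client,0.362,0.437,0.622,0.223,0.388,0.678
F02,Freight Cost,0.319,0.41,0.684,0.242,0.4,0.763
F03,Delivery to Client,0.278,0.323,0.431,0.155,0.274,0.476
F03,Freight Cost,0.292,0.36,0.487,0.218,0.352,0.585
F04,Delivery to Client,0.201,0.22,0.294,0.097,0.164,0.277
F04,Freight Cost,0.193,0.22,0.276,0.129,0.198,0.315
F05,Delivery to Client,0.263,0.303,0.396,0.152,0.268,0.465
F05,Freight Cost,0.328,0.421,0.608,0.249,0.413,0.708
F06,Delivery to Client,0.293,0.348,0.494,0.156,0.278,0.493
F06,Freight Cost,0.296,0.36,0.485,0.224,0.359,0.599
F07,Delivery to Client,0.352,0.437,0.693,0.214,0.384,0.728
F07,Freight Cost,0.327,0.42,0.633,0.249,0.412,0.736
F08,Delivery to Client,0.302,0.358,0.508,0.161,0.285,0.504
F08,Freight Cost,0.252,0.304,0.393,0.187,0.301,0.495
F09,Delivery to Client,0.32,0.384,0.555,0.194,0.347,0.634
F09,Freight Cost,0.266,0.329,0.443,0.193,0.313,0.519
F10,Delivery to Client,0.271,0.315,0.419,0.157,0.277,0.484
F10,Freight Cost,0.351,0.451,0.665,0.269,0.441,0.766
F11,Delivery to Client,0.279,0.328,0.458,0.163,0.29,0.514
F11,Freight Cost,0.307,0.38,0.54,0.228,0.367,0.63
F12,Delivery to Client,0.359,0.446,0.696,0.218,0.393,0.731
F12,Freight Cost,0.33,0.424,0.637,0.252,0.417,0.743
F13,Delivery to Client,0.176,0.186,0.212,0.09,0.155,0.251
F13,Freight Cost,0.206,0.232,0.278,0.144,0.22,0.343
F14,Delivery to Client,0.157,0.159,0.175,0.076,0.127,0.203
F14,Freight Cost,0.182,0.2,0.228,0.124,0.188,0.286
F15,Delivery to Client,0.305,0.359,0.495,0.181,0.319,0.565
F15,Freight Cost,0.259,0.308,0.39,0.191,0.302,0.486
F16,Delivery to Client,0.199,0.206,0.248,0.104,0.171,0.285
F16,Freight Cost,0.169,0.185,0.217,0.114,0.171,0.266
F17,Delivery to Client,0.255,0.293,0.369,0.145,0.257,0.433
F17,Freight Cost,0.321,0.387,0.519,0.245,0.384,0.632
F18,Delivery to Client,0.28,0.333,0.469,0.162,0.291,0.526
F18,Freight Cost,0.29,0.353,0.471,0.214,0.341,0.557
F19,Delivery to Client,0.354,0.439,0.643,0.217,0.39,0.7
F19,Freight Cost,0.343,0.434,0.629,0.26,0.42,0.722
F20,Delivery to Client,0.207,0.221,0.254,0.11,0.187,0.3
F20,Freight Cost,0.185,0.208,0.258,0.123,0.185,0.291
F21,Delivery to Client,0.263,0.305,0.394,0.151,0.266,0.454
F21,Freight Cost,0.328,0.403,0.561,0.251,0.399,0.671
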