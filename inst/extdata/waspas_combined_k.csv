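mode_code,objective,k_l,k_m,k_u
F01,Delivery to Client,0.209,0.293,0.507
F01,Freight Cost,0.273,0.376,0.588
F02,Delivery to Client,0.292,0.413,0.65
F02,Freight Cost,0.281,0.405,0.723
F03,Delivery to Client,0.216,0.299,0.453
F03,Freight Cost,0.255,0.356,0.536
F04,Delivery to Client,0.149,0.192,0.285
F04,Freight Cost,0.161,0.209,0.296
F05,Delivery to Client,0.208,0.285,0.431
F05,Freight Cost,0.288,0.417,0.658
F06,Delivery to Client,0.224,0.313,0.493
F06,Freight Cost,0.26,0.359,0.542
F07,Delivery to Client,0.283,0.411,0.711
F07,Freight Cost,0.288,0.416,0.684
F08,Delivery to Client,0.232,0.322,0.506
F08,Freight Cost,0.22,0.302,0.444
F09,Delivery to Client,0.257,0.366,0.595
F09,Freight Cost,0.229,0.321,0.481
F10,Delivery to Client,0.214,0.296,0.452
F10,Freight Cost,0.31,0.446,0.716
F11,Delivery to Client,0.221,0.309,0.486
F11,Freight Cost,0.268,0.374,0.585
F12,Delivery to Client,0.288,0.419,0.714
F12,Freight Cost,0.291,0.421,0.69
F13,Delivery to Client,0.133,0.171,0.232
F13,Freight Cost,0.175,0.226,0.31
F14,Delivery to Client,0.116,0.143,0.189
F14,Freight Cost,0.153,0.194,0.257
F15,Delivery to Client,0.243,0.339,0.53
F15,Freight Cost,0.225,0.305,0.438
F16,Delivery to Client,0.152,0.188,0.266
F16,Freight Cost,0.141,0.178,0.242
F17,Delivery to Client,0.2,0.275,0.401
F17,Freight Cost,0.283,0.386,0.576
F18,Delivery to Client,0.221,0.312,0.497
F18,Freight Cost,0.252,0.347,0.514
F19,Delivery to Client,0.285,0.414,0.672
F19,Freight Cost,0.301,0.427,0.675
F20,Delivery to Client,0.159,0.204,0.277
F20,Freight Cost,0.154,0.197,0.274
F21,Delivery to Client,0.207,0.286,0.424
F21,Freight Cost,0.29,0.401,0.616
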