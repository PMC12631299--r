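mode_code,objective,theta_norm
F01,Delivery to Client,0.6341
F01,Freight Cost,0.5998
F02,Delivery to Client,0.6929
F02,Freight Cost,0.6645
F03,Delivery to Client,0.6542
F03,Freight Cost,0.5847
F04,Delivery to Client,0.5536
F04,Freight Cost,0.6881
F05,Delivery to Client,0.6554
F05,Freight Cost,0.67490000000000006
F06,Delivery to Client,0.7303
F06,Freight Cost,0.6242
F07,Delivery to Client,0.6739
F07,Freight Cost,0.6525
F08,Delivery to Client,0.6667
F08,Freight Cost,0.7757
F09,Delivery to Client,0.6255
F09,Freight Cost,0.5516
F10,Delivery to Client,0.6647
F10,Freight Cost,0.7296
F11,Delivery to Client,0.7345
F11,Freight Cost,0.7047
F12,Delivery to Client,0.6857
F12,Freight Cost,0.6467
F13,Delivery to Client,0.6813
F13,Freight Cost,0.6468
F14,Delivery to Client,1
F14,Freight Cost,0.6838
F15,Delivery to Client,0.5783
F15,Freight Cost,0.7417
F16,Delivery to Client,0.6666
F16,Freight Cost,1
F17,Delivery to Client,0.6832
F17,Freight Cost,0.6496
F18,Delivery to Client,0.681
F18,Freight Cost,0.5807
F19,Delivery to Client,0.6643
F19,Freight Cost,0.7206
F20,Delivery to Client,0.6636
F20,Freight Cost,0.6471
F21,Delivery to Client,0.6731
F21,Freight Cost,0.6013
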