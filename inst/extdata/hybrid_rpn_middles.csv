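mode_code,objective,rpn_middle
F01,Delivery to Client,109.44
F01,Freight Cost,62.4
F02,Delivery to Client,94.5
F02,Freight Cost,78.4
F03,Delivery to Client,93.6
F03,Freight Cost,66.15
F04,Delivery to Client,163.2
F04,Freight Cost,184.45
F05,Delivery to Client,110
F05,Freight Cost,64.512
F06,Delivery to Client,101.25
F06,Freight Cost,75.6
F07,Delivery to Client,72
F07,Freight Cost,56
F08,Delivery to Client,70
F08,Freight Cost,103.95
F09,Delivery to Client,63
F09,Freight Cost,67.2
F10,Delivery to Client,108
F10,Freight Cost,57.6
F11,Delivery to Client,113.75
F11,Freight Cost,63
F12,Delivery to Client,69.3
F12,Freight Cost,56
F13,Delivery to Client,236.25
F13,Freight Cost,187.2
F14,Delivery to Client,360
F14,Freight Cost,286.875
F15,Delivery to Client,63
F15,Freight Cost,92.4
F16,Delivery to Client,243.36
F16,Freight Cost,252
F17,Delivery to Client,126
F17,Freight Cost,81
F18,Delivery to Client,101.25
F18,Freight Cost,78.75
F19,Delivery to Client,70.4
F19,Freight Cost,64
F20,Delivery to Client,210
F20,Freight Cost,149.5
F21,Delivery to Client,113.4
F21,Freight Cost,63
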