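objective,criterion,wl,wm,wu
Delivery to Client,S,0.47,0.54,0.62
Delivery to Client,O,0.33,0.36,0.39
Delivery to Client,D,0.14,0.17,0.21
Freight Cost,S,0.42,0.48,0.54
Freight Cost,O,0.32,0.35,0.39
Freight Cost,D,0.15,0.18,0.2
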