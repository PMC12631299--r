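mode_code,mode_name
F01,Country Infrastructure
F02,Coordination Failures
F03,INCO Term Misalignment
F04,Shipment Mode Selection
F05,Delivery Scheduling
F06,Storage Conditions
F07,Dosage Errors
F08,Molecule Mismatch
F09,Vendor Reliability
F10,Brand Delays
F11,Delivery Confirmation
F12,Product Misclassification
F13,Unit Miscalculation
F14,Quantity Errors
F15,Customs Delays
F16,Pack Price Discrepancies
F17,Demand Forecasting
F18,Site Distance Delays
F19,First Line Delays
F20,Weight Failures
F21,Insurance Overruns
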