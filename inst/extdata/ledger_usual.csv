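item,category,unit_cost,quantity,capital_lifetime,capital_rate
Overhead,overhead,1.9738,7.64,,
Primary care physician visits,visit,9.63,6.90,,
Specialist visits,visit,9.63,0.74,,
Emergency ambulance service,visit,1.45,12,,
Drugs,consumption,160.48,1,,
Diagnostic and follow-up tests,consumption,29.10,1,,
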