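# Synthetic disease-burden table (thousands of DALYs); stand-in values for
# demonstration only, not GBD estimates.
disease	dalys
Hypertensive heart disease	9100
Ischemic heart disease	28400
Kidney diseases	7600
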