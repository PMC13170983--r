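age_lower,age_upper,sex,norm_utility,source_label
18,44,F,0.91,UK general population EQ-5D-3L norms (packaged default; editable)
45,54,F,0.85,UK general population EQ-5D-3L norms (packaged default; editable)
55,64,F,0.81,UK general population EQ-5D-3L norms (packaged default; editable)
65,74,F,0.78,UK general population EQ-5D-3L norms (packaged default; editable)
75,110,F,0.71,UK general population EQ-5D-3L norms (packaged default; editable)
18,44,M,0.91,UK general population EQ-5D-3L norms (packaged default; editable)
45,54,M,0.85,UK general population EQ-5D-3L norms (packaged default; editable)
55,64,M,0.78,UK general population EQ-5D-3L norms (packaged default; editable)
65,74,M,0.78,UK general population EQ-5D-3L norms (packaged default; editable)
75,110,M,0.75,UK general population EQ-5D-3L norms (packaged default; editable)
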