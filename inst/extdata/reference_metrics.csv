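model,metric,percent
three_class,correct_pct_sporadic,80
three_class,correct_pct_SDHx,100
three_class,correct_pct_VHL,83
three_class,se,94
three_class,sp,80
three_class,ppv,89
three_class,npv,89
three_class,accuracy,89
sdhx_vs_sporadic,se,92
sdhx_vs_sporadic,sp,90
sdhx_vs_sporadic,ppv,92
sdhx_vs_sporadic,npv,90
sdhx_vs_sporadic,accuracy,91
vhl_vs_sporadic,se,100
vhl_vs_sporadic,sp,100
vhl_vs_sporadic,ppv,100
vhl_vs_sporadic,npv,100
vhl_vs_sporadic,accuracy,100
sdhx_vs_vhl,se,100
sdhx_vs_vhl,sp,100
sdhx_vs_vhl,ppv,100
sdhx_vs_vhl,npv,100
sdhx_vs_vhl,accuracy,100
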