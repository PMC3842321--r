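model,truth,predicted,count
three_class,sporadic,sporadic,8
three_class,sporadic,SDHx,1
three_class,sporadic,VHL,1
three_class,SDHx,SDHx,12
three_class,SDHx,sporadic,0
three_class,SDHx,VHL,0
three_class,VHL,VHL,5
three_class,VHL,sporadic,1
three_class,VHL,SDHx,0
sdhx_vs_sporadic,sporadic,sporadic,9
sdhx_vs_sporadic,sporadic,SDHx,1
sdhx_vs_sporadic,SDHx,SDHx,11
sdhx_vs_sporadic,SDHx,sporadic,1
vhl_vs_sporadic,sporadic,sporadic,10
vhl_vs_sporadic,sporadic,VHL,0
vhl_vs_sporadic,VHL,VHL,6
vhl_vs_sporadic,VHL,sporadic,0
sdhx_vs_vhl,SDHx,SDHx,12
sdhx_vs_vhl,SDHx,VHL,0
sdhx_vs_vhl,VHL,VHL,6
sdhx_vs_vhl,VHL,SDHx,0
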