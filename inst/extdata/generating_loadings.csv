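source,model,factor,indicator,loading
caspi,revised_bifactor,p,alc,0.397
caspi,revised_bifactor,p,cann,0.455
caspi,revised_bifactor,p,hd,0.452
caspi,revised_bifactor,p,tob,0.504
caspi,revised_bifactor,p,cd,0.557
caspi,revised_bifactor,p,dep,0.835
caspi,revised_bifactor,p,gad,0.812
caspi,revised_bifactor,p,fears,0.623
caspi,revised_bifactor,p,ocd,0.725
caspi,revised_bifactor,p,mania,0.973
caspi,revised_bifactor,p,schiz,0.819
caspi,revised_bifactor,Ext,alc,0.626
caspi,revised_bifactor,Ext,cann,0.811
caspi,revised_bifactor,Ext,hd,0.709
caspi,revised_bifactor,Ext,tob,0.420
caspi,revised_bifactor,Ext,cd,0.691
caspi,revised_bifactor,Int,dep,0.340
caspi,revised_bifactor,Int,gad,0.497
caspi,revised_bifactor,Int,fears,0.441
simdata,revised_bifactor,p,alc,0.294
simdata,revised_bifactor,p,cann,0.309
simdata,revised_bifactor,p,hd,0.320
simdata,revised_bifactor,p,tob,0.398
simdata,revised_bifactor,p,cd,0.394
simdata,revised_bifactor,p,dep,0.605
simdata,revised_bifactor,p,gad,0.582
simdata,revised_bifactor,p,fears,0.476
simdata,revised_bifactor,p,ocd,0.709
simdata,revised_bifactor,p,mania,0.969
simdata,revised_bifactor,p,schiz,0.805
simdata,revised_bifactor,Ext,alc,0.536
simdata,revised_bifactor,Ext,cann,0.629
simdata,revised_bifactor,Ext,hd,0.577
simdata,revised_bifactor,Ext,tob,0.368
simdata,revised_bifactor,Ext,cd,0.559
simdata,revised_bifactor,Int,dep,0.247
simdata,revised_bifactor,Int,gad,0.388
simdata,revised_bifactor,Int,fears,0.347
caspi,correlated,Ext,alc,0.733
caspi,correlated,Ext,cann,0.885
caspi,correlated,Ext,hd,0.839
caspi,correlated,Ext,tob,0.668
caspi,correlated,Ext,cd,0.909
caspi,correlated,Int,dep,0.972
caspi,correlated,Int,gad,0.934
caspi,correlated,Int,fears,0.704
caspi,correlated,Tht,ocd,0.726
caspi,correlated,Tht,mania,0.982
caspi,correlated,Tht,schiz,0.826
simdata,correlated,Ext,alc,0.604
simdata,correlated,Ext,cann,0.678
simdata,correlated,Ext,hd,0.652
simdata,correlated,Ext,tob,0.545
simdata,correlated,Ext,cd,0.694
simdata,correlated,Int,dep,0.682
simdata,correlated,Int,gad,0.677
simdata,correlated,Int,fears,0.563
simdata,correlated,Tht,ocd,0.709
simdata,correlated,Tht,mania,0.968
simdata,correlated,Tht,schiz,0.805
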