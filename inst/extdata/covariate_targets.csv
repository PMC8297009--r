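source,covariate,factor,value
caspi,VC,p,-0.129
caspi,PR,p,-0.129
caspi,WM,p,-0.183
caspi,PS,p,-0.176
caspi,VC,Ext,-0.084
caspi,PR,Ext,-0.054
caspi,WM,Ext,-0.028
caspi,PS,Ext,-0.035
caspi,VC,Int,0.112
caspi,PR,Int,0.062
caspi,WM,Int,-0.027
caspi,PS,Int,0.019
simdata,VC,p,-0.120
simdata,PR,p,-0.123
simdata,WM,p,-0.176
simdata,PS,p,-0.167
simdata,VC,Ext,-0.120
simdata,PR,Ext,-0.068
simdata,WM,Ext,-0.015
simdata,PS,Ext,-0.035
simdata,VC,Int,0.110
simdata,PR,Int,0.060
simdata,WM,Int,-0.007
simdata,PS,Int,0.032
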