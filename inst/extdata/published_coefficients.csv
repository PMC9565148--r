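rtype,model,term,estimate,t_stat
park,Car,t_auto,-0.286,-93.013
park,MCLS,mcls,10.203,93.013
park,All-Car,t_auto,-0.267,-67.263
park,All-Car,log_acres,1.307,45.585
park,All-Car,playground,4.467,30.248
park,All-Car,volleyball,-0.555,-9.379
park,All-Car,basketball,-0.508,-7.024
park,All-Car,tennis,-0.881,-14.706
park,All-Logsum,mcls,9.547,67.263
park,All-Logsum,log_acres,1.307,45.582
park,All-Logsum,playground,4.466,30.247
park,All-Logsum,volleyball,-0.555,-9.379
park,All-Logsum,basketball,-0.508,-7.024
park,All-Logsum,tennis,-0.881,-14.708
grocery,Car,t_auto,-0.251,-94.328
grocery,MCLS,mcls,8.972,94.329
grocery,All-Car,t_auto,-0.270,-82.644
grocery,All-Car,convenience,-1.343,-6.987
grocery,All-Car,other_nonstandard,-1.418,-9.430
grocery,All-Car,pharmacy,0.330,7.848
grocery,All-Car,ethnic_market,-0.887,-9.080
grocery,All-Car,other_merchandise,0.909,19.288
grocery,All-Car,n_registers,0.087,40.073
grocery,All-Car,n_selfcheckout,0.020,8.207
grocery,All-Logsum,mcls,9.643,82.645
grocery,All-Logsum,convenience,-1.343,-6.987
grocery,All-Logsum,other_nonstandard,-1.418,-9.429
grocery,All-Logsum,pharmacy,0.330,7.850
grocery,All-Logsum,ethnic_market,-0.887,-9.082
grocery,All-Logsum,other_merchandise,0.909,19.291
grocery,All-Logsum,n_registers,0.087,40.074
grocery,All-Logsum,n_selfcheckout,0.020,8.206
library,Car,t_auto,-0.303,-91.448
library,MCLS,mcls,10.814,91.447
library,All-Car,t_auto,-0.313,-72.838
library,All-Car,offers_classes,-0.819,-12.050
library,All-Car,genealogy,-0.867,-20.844
library,All-Car,log_sqft,1.219,44.555
library,All-Logsum,mcls,11.195,72.836
library,All-Logsum,offers_classes,-0.819,-12.051
library,All-Logsum,genealogy,-0.867,-20.840
library,All-Logsum,log_sqft,1.219,44.552
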