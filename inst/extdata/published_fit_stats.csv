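rtype,model,n_obs,loglik,rho_sq,n_coef
park,Car,9119,-8945.6,0.591,1
park,MCLS,9119,-8944.8,0.591,1
park,Attributes,9119,-11954.7,0.453,5
park,All-Car,9119,-4603.5,0.789,6
park,All-Logsum,9119,-4603.2,0.789,6
grocery,Car,10000,-14256.7,0.405,1
grocery,MCLS,10000,-14257.0,0.405,1
grocery,Attributes,10000,-20199.6,0.158,5
grocery,Size,10000,-19031.4,0.206,7
grocery,All-Car,10000,-10542.9,0.560,8
grocery,All-Logsum,10000,-10542.9,0.560,8
library,Car,10000,-11198.0,0.533,1
library,MCLS,10000,-11197.5,0.533,1
library,Attributes,10000,-17667.4,0.263,3
library,All-Car,10000,-9389.7,0.608,4
library,All-Logsum,10000,-9389.6,0.608,4
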