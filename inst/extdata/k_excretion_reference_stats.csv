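database,variable,n,mean,sd,min,max
urinary,k_ur,45,202.5,92.1,70.2,476.0
urinary,dmi,45,16.9,5.4,4.4,27.6
urinary,k_intake,45,316.6,144.3,105.3,686.0
urinary,dietary_k,45,1.7,0.66,0.79,2.73
urinary,water_intake,18,83.6,44.2,20.9,146.6
urinary,urine_volume,26,21.1,8.02,10.5,39.9
urinary,milk_yield,20,31.2,6.20,21.6,41.5
fecal,k_fa,54,43.5,21.0,15.5,94.7
fecal,dmi,54,17.9,5.8,4.4,27.6
fecal,k_intake,54,282.0,125.8,105.3,583.0
fecal,dietary_k,49,1.5,0.50,0.79,2.46
fecal,milk_yield,37,30.0,7.80,20.1,41.6
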