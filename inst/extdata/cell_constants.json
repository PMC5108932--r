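{"gK1":0.5,"gNa":0.5,"kmK1":10,"Ko":5.4,"Cm":0.095,"T":310,"Nao":140,"Cao":2,"gKr1":0.0021,"gKr2":0.0013,"gKs":0.0026,"gto":0.005,"gtos":0,"gpNa":0.004,"gbNa":0.0006,"gbCa":0.00025,"iNaKmax":0.7,"KmK":1,"KmNa":40,"kNaCa":0.0005,"gammaNaCa":0.5,"nNaCa":3,"dNaCa":0,"FRANaCa":0.001,"FrICa":1,"PCaL":0.1,"PCaK":0.002,"PCaNa":0.01,"speed_d":3,"speed_f":0.3,"Kmf2":0.0002,"Rf2":1,"Kmf2ds":0.001,"Rf2ds":20,"KmCaCyt":0.0005,"KmCaDs":0.01,"KmRel":250,"KleakRate":0.05,"ActRateMax":500,"InactRateBase":60,"InactRateCa":500,"SpeedRelSlow":5,"VSpeedRel":-50,"alphaUp":0.4,"betaUp":0.03,"Kcyca":0.0003,"Kxcs":0.4,"Ksrca":0.5,"Ktrans":50,"radius":0.012,"length":0.074,"ViRatio":0.49,"VdsRatio":0.1,"VrelRatio":0.1,"VupRatio":0.01,"KdecayDs":10,"alphaCalmod":100000,"betaCalmod":50,"CalmodTot":0.02,"alphaTrop":100000,"betaTrop":200,"TropTot":0.05,"PkNa":0.03,"naRatioMh":0.12,"rectK1":1.25}
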