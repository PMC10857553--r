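patient,w,s,f,data,mae,mse,mape,max,fit
A,20,10,20,45339,0.89,1.78,0.99,26,12.41
A,20,10,30,43617,0.94,2.04,1.05,28,13.64
A,20,10,40,42020,0.98,2.22,1.09,28,14.20
A,20,5,20,71878,1.02,2.33,1.15,26,14.22
A,10,10,20,71878,1.14,2.95,1.29,27,16.34
B,20,10,20,52243,0.49,0.52,0.51,24,7.57
B,20,10,30,50687,0.51,0.55,0.53,32,9.30
B,20,5,20,72796,0.53,0.65,0.56,27,8.61
B,20,10,40,49227,0.53,0.61,0.56,28,8.71
B,10,10,20,72796,0.56,0.75,0.59,28,9.14
C,20,10,20,83559,0.61,0.83,0.69,26,9.17
C,20,10,40,80992,0.63,0.89,0.71,27,9.59
C,20,10,30,82245,0.63,0.90,0.72,27,9.62
C,20,5,20,99748,0.63,0.90,0.72,26,9.44
C,10,10,20,99748,0.65,0.95,0.74,27,9.80
D,20,10,20,53802,0.85,1.60,0.94,25,11.63
D,20,10,30,52187,0.88,1.74,0.96,25,12.05
D,20,5,20,75128,0.93,1.92,1.03,26,12.90
D,20,10,40,50664,0.94,2.03,1.03,27,13.36
D,10,10,20,75128,1.03,2.37,1.15,26,14.32
E,20,10,20,101200,0.52,0.57,0.55,14,5.78
E,20,5,20,128041,0.52,0.59,0.56,16,6.26
E,10,10,20,128041,0.55,0.67,0.60,25,8.35
E,10,5,20,147778,0.56,0.69,0.61,26,8.63
E,20,10,30,98965,0.56,0.67,0.61,27,8.79
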