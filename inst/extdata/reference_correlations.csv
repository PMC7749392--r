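parameter,family,r_A,p_A,r_B,p_B
PMT,aggregation,-0.545,0.001,-0.515,0.001
BEM,aggregation,0.594,0.001,0.524,0.001
peak30,aggregation,0.212,NA,0.222,NA
peak180,aggregation,-0.437,0.002,-0.393,0.007
peak30_peak180,aggregation,0.540,0.001,0.484,0.001
y0,aggregation,0.059,NA,-0.040,NA
xc1,aggregation,-0.560,0.001,-0.525,0.001
A,aggregation,0.166,NA,0.143,NA
w,aggregation,-0.347,0.018,-0.292,0.049
k2,aggregation,0.139,NA,0.199,NA
xc2,aggregation,0.352,0.016,0.349,0.017
B,aggregation,-0.257,NA,-0.255,0.087
k3,aggregation,-0.218,NA,-0.146,NA
xc3,aggregation,-0.506,0.001,-0.509,0.001
E_Rmax,extension,0.442,0.002,0.521,0.001
R_max,extension,0.150,NA,0.066,NA
A_Rmax,extension,0.398,0.002,0.396,0.002
E_max,extension,0.516,0.001,0.614,0.001
A_max,extension,0.493,0.001,0.499,0.001
E_Rmax_R_max,extension,0.235,NA,0.370,NA
gliadin_hmw,protein,0.026,NA,0.029,NA
gliadin_mmw,protein,0.433,0.003,0.390,0.007
gliadin_lmw,protein,0.370,0.011,0.374,0.010
gliadin_total,protein,0.327,0.026,0.301,0.042
glutenin_hmw,protein,-0.033,NA,0.061,NA
glutenin_mmw,protein,-0.507,0.001,-0.487,0.001
glutenin_lmw,protein,-0.309,0.037,-0.297,0.045
glutenin_total,protein,-0.327,0.026,-0.301,0.042
glia_glut_ratio,protein,0.327,0.026,0.301,0.042
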