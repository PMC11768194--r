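sample,cultivar,substitution_pct,t_hydr,t1,c1,water_absorption,amplitude,stability,slope_alpha,c2,slope_beta,c3,t3,gelling_mid,c4,c5
control,none,0,3.63,7.08,1.10,62.8,0.073,6.97,-0.095,0.52,0.110,1.61,21.7,66.0,1.29,1.89
cavendish_5,cavendish,5,4.85,4.19,1.10,61.7,0.092,6.87,-0.100,0.49,0.151,1.71,22.5,66.0,1.29,1.95
ladyfinger_5,ladyfinger,5,1.13,5.91,1.13,62.8,0.101,7.04,-0.099,0.51,0.155,1.73,22.5,68.0,1.37,2.13
ducasse_5,ducasse,5,1.11,5.28,1.12,62.8,0.115,7.02,-0.100,0.50,0.147,1.74,22.3,66.0,1.26,1.86
cavendish_10,cavendish,10,1.31,5.66,1.09,61.7,0.107,6.85,-0.111,0.43,0.219,1.77,22.9,69.2,1.38,2.13
ladyfinger_10,ladyfinger,10,1.36,5.91,1.08,63.9,0.105,7.29,-0.085,0.47,0.174,1.72,22.7,68.1,1.41,2.19
ducasse_10,ducasse,10,1.57,5.50,1.10,62.8,0.114,7.16,-0.102,0.46,0.184,1.75,22.6,68.0,1.23,1.85
cavendish_15,cavendish,15,1.36,6.54,1.05,61.7,0.094,7.23,-0.105,0.43,0.325,1.84,22.8,70.1,1.45,2.28
ladyfinger_15,ladyfinger,15,1.70,7.68,0.94,67.0,0.109,7.31,-0.055,0.42,0.197,1.70,22.7,68.1,1.45,2.22
ducasse_15,ducasse,15,1.43,6.14,1.07,63.5,0.110,7.26,-0.090,0.42,0.229,1.74,22.6,69.2,1.24,1.96
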