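variant,kd_M,kon,kon_se,koff,koff_se
wild_type,2.22e-10,2.48e6,0.01e6,5.49e-4,0.01e-4
R3,5.49e-11,8.79e6,0.02e6,4.83e-4,0.01e-4
R5,2.03e-12,7.19e6,0.05e6,1.46e-5,0.01e-5
K5,8.04e-12,5.44e7,0.04e7,4.37e-4,0.01e-4
D5,9.69e-10,7.64e5,0.04e5,7.40e-4,0.02e-4
E5,1.52e-9,2.79e5,0.01e5,4.24e-4,0.01e-4
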