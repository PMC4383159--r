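iterations,roi,mse_ifsa,psnr_ifsa,time_ifsa,mse_ifa,psnr_ifa,time_ifa,d_psnr_percent,csr_percent
200,1,2.685,43.842,31.205,2.687,43.838,8.323,0.0091,73.327
200,2,1.800,45.578,30.549,1.802,45.573,8.167,0.0109,73.266
200,3,1.924,45.289,30.740,1.930,45.274,8.219,0.0110,73.556
200,4,2.047,45.020,30.455,2.052,45.008,8.157,0.0266,73.465
200,5,2.525,44.109,31.095,2.530,44.100,8.251,0.0204,73.465
200,6,2.693,43.828,30.690,2.699,43.818,8.198,0.0228,73.287
200,7,1.676,45.889,30.424,1.681,45.876,8.115,0.0283,73.329
200,8,2.020,45.078,30.439,2.027,45.063,8.115,0.0332,73.340
200,9,1.741,45.723,30.937,1.743,45.718,8.230,0.0111,73.398
200,10,1.718,45.781,31.315,1.725,45.764,8.229,0.0371,73.722
300,1,2.685,43.842,31.205,2.685,43.842,12.485,0.0000,59.990
300,2,1.800,45.578,30.549,1.800,45.578,12.250,0.0000,59.900
300,3,1.924,45.289,30.740,1.926,45.284,12.329,0.0110,59.892
300,4,2.047,45.020,30.455,2.047,45.021,12.235,-0.0022,59.825
300,5,2.525,44.109,31.095,2.525,44.109,12.376,0.0000,60.199
300,6,2.693,43.828,30.690,2.693,43.828,12.297,0.0000,59.931
300,7,1.676,45.889,30.424,1.677,45.887,12.173,0.0044,59.989
300,8,2.020,45.078,30.439,2.022,45.073,12.173,0.0111,60.008
300,9,1.741,45.723,30.937,1.741,45.723,12.345,0.0000,60.096
300,10,1.718,45.781,31.315,1.718,45.783,12.344,-0.0043,61.801
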