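species,pair_id,rl_short_mean,rl_short_sd,rl_long_mean,rl_long_sd,rl_total_mean,rl_total_sd,ar_mean,ar_sd,type,satellite_arm,cpd_percent,cpd_percent_sd,sgish_short_percent,sgish_short_sd,sgish_long_percent,sgish_long_sd,sgish_total_percent,sgish_total_sd
gladiata,1,5.25,0.23,6.70,0.24,11.95,0.41,1.28,0.05,m,none,1.53,0.27,3.19,0.19,4.17,0.13,7.35,0.22
gladiata,2,4.43,0.10,6.39,0.36,10.82,0.31,1.44,0.10,m,none,1.93,0.15,3.07,0.33,2.96,0.19,6.03,0.38
gladiata,3,4.72,0.37,5.69,0.19,10.40,0.28,1.21,0.12,m,none,1.63,0.17,1.44,0.28,3.56,0.13,5.00,0.28
gladiata,4,4.63,0.20,5.57,0.17,10.20,0.17,1.21,0.08,m,none,1.67,0.14,3.19,0.22,2.50,0.15,5.69,0.09
gladiata,5,3.61,0.08,5.53,0.09,9.15,0.16,1.53,0.02,m,none,1.76,0.19,3.61,0.08,1.94,0.24,5.55,0.31
gladiata,6,3.71,0.46,5.11,0.22,8.83,0.61,1.39,0.16,m,short,1.54,0.10,3.71,0.46,2.79,0.26,6.50,0.67
gladiata,7,4.14,0.20,4.50,0.26,8.64,0.38,1.09,0.06,m,short,1.14,0.18,4.14,0.20,2.13,0.32,6.27,0.50
gladiata,8,3.42,0.25,4.68,0.12,8.11,0.21,1.38,0.13,m,none,1.93,0.27,2.33,0.23,3.01,0.14,5.34,0.31
gladiata,9,3.20,0.08,4.53,0.20,7.73,0.18,1.42,0.08,m,none,1.79,0.11,3.20,0.08,1.77,0.21,4.97,0.25
gladiata,10,3.39,0.10,4.31,0.29,7.70,0.38,1.27,0.06,m,none,1.36,0.16,1.62,0.28,2.55,0.32,4.18,0.31
gladiata,11,2.44,0.16,4.03,0.21,6.47,0.27,1.65,0.13,m,none,1.32,0.12,2.43,0.18,1.73,0.17,4.15,0.33
ensiformis,1,5.58,0.23,7.02,0.38,12.60,0.18,1.26,0.11,m,none,2.54,0.57,3.18,0.17,3.99,0.29,7.17,0.36
ensiformis,2,4.43,0.18,6.62,0.28,11.05,0.38,1.50,0.07,m,none,2.32,0.63,2.53,0.29,3.14,0.20,5.66,0.40
ensiformis,3,5.02,0.16,5.33,0.60,10.35,0.51,1.06,0.14,m,none,2.14,0.68,3.77,0.24,2.32,0.11,6.10,0.29
ensiformis,4,4.68,0.16,5.35,0.43,10.03,0.53,1.14,0.08,m,none,1.93,0.40,1.67,0.21,3.57,0.19,5.24,0.37
ensiformis,5,3.49,0.19,5.36,0.28,8.85,0.29,1.54,0.13,m,none,1.80,0.23,2.12,0.17,2.13,0.32,4.25,0.31
ensiformis,6,3.96,0.29,4.80,0.25,8.76,0.46,1.22,0.08,m,short,2.08,0.51,3.96,0.29,2.87,0.24,6.83,0.31
ensiformis,7,3.65,0.25,4.46,0.16,8.11,0.15,1.23,0.13,m,short,1.45,0.18,3.65,0.25,2.48,0.55,6.13,0.57
ensiformis,8,3.76,0.25,4.25,0.28,8.01,0.41,1.13,0.10,m,none,1.88,0.33,1.65,0.22,2.73,0.15,4.38,0.34
ensiformis,9,2.99,0.23,4.73,0.32,7.72,0.23,1.59,0.22,m,none,1.76,0.20,2.99,0.23,1.81,0.19,4.80,0.35
ensiformis,10,3.35,0.24,4.34,0.22,7.69,0.44,1.30,0.05,m,none,1.67,0.18,2.06,0.15,2.56,0.26,4.62,0.37
ensiformis,11,2.59,0.27,4.23,0.19,6.82,0.44,1.64,0.12,m,none,1.68,0.08,2.59,0.27,1.76,0.38,4.35,0.61
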