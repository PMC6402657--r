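subject,pair,D1,D2,D3,D4,D5,D6
S1,1-2,2.14,2.52,1.84,2.24,2.26,2.77
S1,1-3,1.45,1.20,1.35,0.79,1.21,1.61
S1,1-4,2.15,1.94,3.63,2.38,2.47,3.50
S1,2-3,2.26,2.54,1.90,1.45,1.82,3.29
S1,2-4,0.86,1.06,1.32,1.12,0.96,1.85
S1,3-4,2.23,1.92,3.68,1.51,1.95,4.07
S2,1-2,2.64,1.54,1.30,1.88,0.76,1.74
S2,1-3,1.20,0.96,0.70,1.14,0.88,1.33
S2,1-4,2.22,2.13,0.95,1.52,0.97,0.92
S2,2-3,2.30,1.61,1.26,1.02,1.31,2.94
S2,2-4,1.20,1.01,0.48,0.38,0.41,0.57
S2,3-4,2.02,2.34,0.96,0.86,1.76,1.62
S3,1-2,1.43,1.63,2.01,1.51,1.48,1.49
S3,1-3,0.87,1.14,1.29,0.86,1.04,1.20
S3,1-4,2.58,1.57,2.36,1.32,1.31,1.15
S3,2-3,1.45,1.52,1.64,1.49,1.18,1.94
S3,2-4,2.07,1.01,1.46,1.11,0.72,0.90
S3,3-4,2.41,1.35,1.78,1.19,0.97,1.38
S4,1-2,3.64,3.73,2.56,2.66,3.02,3.66
S4,1-3,1.42,1.92,1.75,1.70,3.67,1.75
S4,1-4,3.57,3.17,2.92,3.45,3.65,3.05
S4,2-3,3.04,5.05,3.71,3.41,4.39,3.14
S4,2-4,1.81,1.97,1.47,1.64,1.03,1.29
S4,3-4,3.04,4.39,4.33,4.52,5.42,2.67
S5,1-2,3.40,2.89,3.74,3.46,3.69,4.94
S5,1-3,0.95,1.09,1.38,2.02,1.91,2.45
S5,1-4,3.48,3.09,6.45,3.57,4.23,5.04
S5,2-3,3.70,2.85,2.87,6.39,4.74,6.58
S5,2-4,1.04,0.62,1.02,0.86,0.80,1.03
S5,3-4,3.82,3.08,5.00,6.67,5.49,6.77
S6,1-2,1.31,2.11,2.23,2.67,3.16,2.07
S6,1-3,0.62,1.28,1.04,1.44,1.34,0.87
S6,1-4,1.16,1.97,1.83,2.24,2.58,1.70
S6,2-3,0.96,2.53,1.30,2.78,1.59,1.61
S6,2-4,0.56,1.22,0.72,1.37,0.97,0.99
S6,3-4,0.82,2.30,1.04,2.28,1.27,1.29
S7,1-2,2.41,3.54,2.22,2.09,1.58,3.71
S7,1-3,0.73,0.94,0.70,1.02,0.74,2.35
S7,1-4,1.83,3.41,2.49,2.20,1.45,3.38
S7,2-3,1.80,1.74,1.90,2.01,1.70,3.51
S7,2-4,0.61,0.86,0.92,0.59,0.45,0.68
S7,3-4,1.29,1.59,2.03,2.02,1.48,3.04
S8,1-2,1.67,1.11,1.55,1.06,1.11,0.93
S8,1-3,1.27,0.91,1.20,0.65,0.85,0.74
S8,1-4,1.45,0.79,1.32,0.90,0.98,0.80
S8,2-3,1.80,1.35,1.63,1.08,1.38,1.42
S8,2-4,1.60,0.90,1.39,1.16,1.24,1.19
S8,3-4,1.50,0.91,1.33,0.87,1.16,1.18
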