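"name","adduct","theoretical_mz"
"PE 32:0","[M+H]+",692.52248
"PE 34:0","[M+H]+",720.55378
"PE 34:1","[M+H]+",718.53813
"PE 36:1","[M+H]+",746.56943
"PE 36:2","[M+H]+",744.55378
"PE 36:4","[M+H]+",740.52248
"PE 38:4","[M+H]+",768.55378
"PE 38:6","[M+H]+",764.52248
"PE 40:6","[M+H]+",792.55378
"PE O-36:5","[M+H]+",724.52757
"PE O-38:5","[M+H]+",752.55887
"PC 32:0","[M+H]+",734.56943
"PC 34:1","[M+H]+",760.58508
"PC 36:2","[M+H]+",786.60073
"PC 34:1-CH3","[M+H]+",746.56943
"LPE 18:1","[M+H]+",480.30847
"LPE 22:6","[M+H]+",526.29282
"PS 40:6","[M+H]+",836.54361
"Cer 42:1;2","[M+H]+",650.64457
"Cer 42:2;2","[M+H]+",648.62892
"HexCer 40:1;2","[M+H]+",784.6661
"HexCer 42:2;2","[M+H]+",810.68175
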