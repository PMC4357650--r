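observed_mz,name,core_nine
1257.473,Man5GlcNAc2,TRUE
1905.697,Man9GlcNAc2,TRUE
1743.643,Man8GlcNAc2,TRUE
1581.587,Man7GlcNAc2,TRUE
1850.730,Hex4HexNAc5dHex1,TRUE
2304.909,Hex5HexNAc5dHex3,TRUE
2158.844,Hex5HexNAc5dHex2,TRUE
1419.532,Man6GlcNAc2,TRUE
1809.69,Hex5HexNAc4dHex1,TRUE
1663.632,Hex5HexNAc4,FALSE
2816.115,Hex6HexNAc6dHex4,FALSE
1485.591,Hex3HexNAc4dHex1,FALSE
1688.663,Hex3HexNAc5dHex1,FALSE
2012.773,Hex5HexNAc5dHex1,FALSE
1647.635,Hex4HexNAc4dHex1,FALSE
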