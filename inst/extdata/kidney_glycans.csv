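name,hex,hexnac,dhex,neuac,neugc
Man5GlcNAc2,5,2,0,0,0
Man6GlcNAc2,6,2,0,0,0
Man7GlcNAc2,7,2,0,0,0
Man8GlcNAc2,8,2,0,0,0
Man9GlcNAc2,9,2,0,0,0
Hex5HexNAc4,5,4,0,0,0
Hex5HexNAc4dHex1,5,4,1,0,0
Hex4HexNAc5dHex1,4,5,1,0,0
Hex5HexNAc5dHex2,5,5,2,0,0
Hex5HexNAc5dHex3,5,5,3,0,0
Hex3HexNAc4dHex1,3,4,1,0,0
Hex3HexNAc5dHex1,3,5,1,0,0
Hex4HexNAc4dHex1,4,4,1,0,0
Hex5HexNAc5dHex1,5,5,1,0,0
Hex6HexNAc6dHex4,6,6,4,0,0
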