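alias,canonical
Maestrichtian,Maastrichtian
Ionian,Chibanian
Middle Pleistocene,Chibanian
Tarantian,Late Pleistocene
Upper Pleistocene,Late Pleistocene
Recent,Holocene
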