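species,gestation,brain_mass
Homo sapiens,275,1330
Pan troglodytes,227,390
Pan paniscus,240,340
Gorilla gorilla,257,490
Pongo pygmaeus,260,390
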