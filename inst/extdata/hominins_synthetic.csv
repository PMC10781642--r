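species,brain_mass,neonatal_body_mean,neonatal_body_min,neonatal_body_max,observed_gestation
Ardipithecus ramidus,280,1932,1796.76,1989.97,NA
Australopithecus afarensis,434,2127.5,1978.575,2255.15,NA
Australopithecus africanus,448,2185,2032.05,2316.1,NA
Homo habilis,600,2357.5,2192.475,2498.95,NA
Homo erectus,900,2760,2566.8,2925.6,NA
Homo heidelbergensis,1200,3277.5,3048.075,3474.15,NA
Homo neanderthalensis,1400,3599.5,3262.54,3815.47,NA
Homo sapiens,1330,3300,3200,3400,275
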