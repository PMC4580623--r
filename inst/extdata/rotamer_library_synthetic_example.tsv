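AA PHI_BIN PSI_BIN PROB CHI1 CHI2 CHI3 CHI4
L -60 -50 0.50 -65.2 176.1 NA NA
L -60 -50 0.28 -172.4 64.8 NA NA
L -60 -50 0.12 -60.0 -60.0 NA NA
L -60 -40 0.52 -64.8 175.5 NA NA
L -60 -40 0.27 -173.0 65.5 NA NA
S -60 -50 0.48 63.1 NA NA NA
S -60 -50 0.30 -62.7 NA NA NA
S -60 -50 0.17 -178.9 NA NA NA
V -60 -50 0.62 175.8 NA NA NA
V -60 -50 0.25 -61.4 NA NA NA
V -60 -50 0.08 62.0 NA NA NA
K -60 -50 0.30 -62.0 179.0 178.5 179.9
K -60 -50 0.22 -178.0 179.5 178.0 -179.5
F -60 -50 0.55 -65.0 92.0 NA NA
F -60 -50 0.40 -178.0 78.0 NA NA
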