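# domain_map_version: mtor-6bcx-lit-1.0
# MTOR (UniProt P42345, 2549 aa) domain boundaries, literature convention for
# the cryo-EM deposition family. Provisional: figure-panel residue ranges in
# the source analysis are not printed in machine-readable form.
domain	start	end
N-HEAT	1	928
M-HEAT	929	1381
FAT	1382	2014
FRB	2015	2114
Kinase N-Lobe	2115	2252
Kinase C-Lobe	2253	2516
FATC	2517	2549
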