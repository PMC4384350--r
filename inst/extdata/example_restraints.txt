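# Long-range distance restraints, whitespace-delimited:
#   res1 atom1 res2 atom2 lower upper [tag]
# residues 1-based, distances in Angstrom, atoms in {N,H,CA,HA,C,O,CB}.
# An HA..carbonyl-O contact pairing two helices:
5  HA 17 O  2.0 3.5 pairing
# Three CB..CB contacts emulating disulfide bridges:
7  CB 37 CB 3.5 6.5 ss
23 CB 33 CB 3.5 6.5 ss
26 CB 46 CB 3.5 6.5 ss
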