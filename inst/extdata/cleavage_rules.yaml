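# Protease cleavage rules in the package's P1 / P1'-blocker grammar.
# p1_residues: residues whose C-terminal peptide bond is cut.
# p1prime_blockers: residues that veto the cut when immediately C-terminal.
pepsin_pH1.3:
  p1_residues: FL
  p1prime_blockers: P
pepsin_pH2:
  p1_residues: FLWY
  p1prime_blockers: P
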