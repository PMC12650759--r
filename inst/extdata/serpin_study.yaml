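# Serpin inhibition-cycle study configuration.
#
# Five crystallographic forms of the serpin/protease inhibition process.
# Sheet strand ranges are inclusive author-numbered intervals; entries whose
# name ends in "_incorp" add the strands incorporated after loop insertion
# (the cleaved reactive-loop fragment) to the no-incorporation selection.
#
# Domain boundaries (D1 = mainly-beta roll, D2 = alpha-beta sandwich) are
# not part of this file's provenance: fill them in from an external domain
# classification (e.g. CATH) before running domain-level rows (~ = unset).
# Chain identifiers for 1QLP, 2ANT and 1EZX should be verified against the
# deposited files before use; 1K9O groupings (serpin = chain I, protease =
# chain E) are established.
study: serpin
cutoff: 9
k_grid: {max: 10, step: 0.1}
forms:
  - form: NATIVE
    pdb_id: 1QLP
    serpin_chains: [A]
    protease_chains: []
    domains: {D1: ~, D2: ~}
    sheets:
      - {name: sheet_A, parent: D1,
         ranges: "A:112-121,A:141-145,A:182-190,A:291-298,A:330-340"}
      - {name: sheet_B, parent: D2,
         ranges: "A:218-232,A:236-244,A:247-255,A:370-376,A:382-388"}
    rcl: ~
  - form: LATENT
    pdb_id: 2ANT
    serpin_chains: [L]
    protease_chains: []
    domains: {D1: ~, D2: ~}
    sheets:
      - {name: sheet_A, parent: D1,
         ranges: "L:140-149,L:167-173,L:213-221,L:323-329"}
      - {name: sheet_A_incorp, parent: D1,
         ranges: "L:140-149,L:167-173,L:213-221,L:323-329,L:364-375"}
      - {name: sheet_B, parent: D2,
         ranges: "L:256-262,L:268-273,L:278-285,L:408-414,L:419-426"}
    rcl: ~
  - form: MICHAELIS
    pdb_id: 1K9O
    serpin_chains: [I]
    protease_chains: [E]
    domains: {D1: ~, D2: ~}
    sheets:
      - {name: sheet_A, parent: D1,
         ranges: "I:101-109,I:129-133,I:172-179,I:287-291,I:326-332"}
      - {name: sheet_B, parent: D2,
         ranges: "I:217-222,I:227-233,I:239-246,I:367-372,I:377-383"}
    rcl: "I:346-356"
  - form: COVALENT
    pdb_id: 1EZX
    serpin_chains: [A, B]
    protease_chains: [C]
    domains: {D1: ~, D2: ~}
    sheets:
      - {name: sheet_A, parent: D1,
         ranges: "A:111-121,A:182-193,A:291-298,A:327-340"}
      - {name: sheet_A_incorp, parent: D1,
         ranges: "A:111-121,A:182-193,A:291-298,A:327-340,A:344-357"}
      - {name: sheet_B, parent: D2,
         ranges: "A:227-232,A:237-243,A:248-255"}
      - {name: sheet_B_incorp, parent: D2,
         ranges: "A:227-232,A:237-243,A:248-255,B:370-376,B:382-388"}
    rcl: ~
  - form: CLEAVED
    pdb_id: 7API
    serpin_chains: [A, B]
    protease_chains: []
    domains: {D1: ~, D2: ~}
    sheets:
      - {name: sheet_A, parent: D1,
         ranges: "A:110-121,A:141-145,A:182-193,A:291-298,A:327-340"}
      - {name: sheet_A_incorp, parent: D1,
         ranges: "A:110-121,A:141-145,A:182-193,A:291-298,A:327-340,A:344-357"}
      - {name: sheet_B, parent: D2,
         ranges: "A:228-232,A:238-244,A:248-255"}
      - {name: sheet_B_incorp, parent: D2,
         ranges: "A:228-232,A:238-244,A:248-255,B:370-375,B:381-388"}
    rcl: ~
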