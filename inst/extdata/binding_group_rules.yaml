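# Default DNA-binding specificity rule table.
#
# Groups are matched in order; the first group whose every
# (position -> allowed residues) constraint holds wins, so specific groups
# precede the generic fallback (group I, plain N at -18 / R|K at -10).
# Only the group XI rule (hydrophobic Ile at -10 instead of Arg/Lys) and
# the group IX rule (Lys at the -18 anchor) are literature-stated; the
# single-position -6 keys for groups II-VIII and X are synthetic
# placeholders standing in for the full per-group residue table, kept as
# editable data. Residue letters are quoted ("N", "Y") because bare N/Y
# are YAML booleans.
groups:
  - label: XI
    rules:
      "-18": ["N"]
      "-10": ["I"]
  - label: IX
    rules:
      "-18": ["K"]
      "-10": ["R", "K"]
  - label: X
    rules:
      "-18": ["N"]
      "-10": ["R", "K"]
      "-6": ["Q"]
  - label: VIII
    rules:
      "-18": ["N"]
      "-10": ["R", "K"]
      "-6": ["M"]
  - label: VII
    rules:
      "-18": ["N"]
      "-10": ["R", "K"]
      "-6": ["C"]
  - label: VI
    rules:
      "-18": ["N"]
      "-10": ["R", "K"]
      "-6": ["W"]
  - label: V
    rules:
      "-18": ["N"]
      "-10": ["R", "K"]
      "-6": ["Y"]
  - label: IV
    rules:
      "-18": ["N"]
      "-10": ["R", "K"]
      "-6": ["A"]
  - label: III
    rules:
      "-18": ["N"]
      "-10": ["R", "K"]
      "-6": ["G"]
  - label: II
    rules:
      "-18": ["N"]
      "-10": ["R", "K"]
      "-6": ["T"]
  - label: I
    rules:
      "-18": ["N"]
      "-10": ["R", "K"]
classes:
  breakers: ["P"]
  initiators: ["L"]
  sub18: ["K"]
  sub10: ["I"]
  histidine_basic: false
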