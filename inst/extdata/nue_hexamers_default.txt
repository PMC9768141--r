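# Near-upstream element (NUE) hexamers — literature-flavored defaults.
# AATAAA (the canonical AAUAAA signal, as DNA) plus common single-
# substitution variants. These are user-overridable stand-ins, not a
# reproduction of any published element compilation; supply an explicit
# dictionary for cross-study comparisons.
AATAAA
AATAAT
AATAAG
AATACA
AATATA
AATGAA
ATTAAA
TATAAA
GATAAA
CATAAA
AAGAAA
AACAAA
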