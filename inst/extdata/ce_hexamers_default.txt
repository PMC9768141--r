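# Cleavage-element (CE) hexamers — literature-flavored defaults: U-rich
# hexamers centered on a YA dinucleotide (positions 3-4), echoing the
# pyrimidine(Y)A cleavage-site context of plant pre-mRNAs. User-overridable
# stand-ins, not a reproduction of any published compilation.
TTTATT
TTCATT
TGTATT
ATTATT
TCTATT
TTTAAT
TTTACT
TTCAAT
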