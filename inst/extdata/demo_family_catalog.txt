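# Demo neuropeptide family catalog (synthetic reference peptides).
# Family names follow well-known bilaterian/lophotrochozoan neuropeptide
# families; the reference peptide sequences are short synthetic stand-ins
# chosen to exercise the classifier, not curated biological sequences.
# Format: blank-line-separated stanzas with family:, tier:, and at least
# one of motif: (x = wildcard) or peptides: (whitespace-separated).

family: insulin-like
tier: eumetazoan
peptides: GIVDECCFRPCSLDVLLSYC

family: myoinhibitory-peptide
tier: protostome
motif: FxFamide
peptides: AWQSLQSGW GWQDLQSGW

family: FMRFamide-like
tier: bilaterian
motif: FRWamide
peptides: AFRW SFRW TFRW

family: FILamide
tier: lophotrochozoan
motif: FILamide
peptides: NSQFIL TDSFIL

family: elevenin
tier: protostome
peptides: PDCRKFVFAPICRGVAA

family: sCAP
tier: annelid
peptides: NQDSTPFNSAW

family: achatin
tier: lophotrochozoan
motif: GFxamide

family: novel-repeat
tier: species_specific
motif: WNQamide
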