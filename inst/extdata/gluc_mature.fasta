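>GLuc_mature mature Gaussia princeps luciferase (UniProtKB Q9BLZ2, 17-residue secretion tag removed, E100A G103R)
KPTENNEDFNIVAVASNFATTDLDADRGKLPGKKLPLEVLKEMEANARKAGCTRGCLICL
SHIKCTPKMKKFIPGRCHTYEGDKESAQGGIGEAIVDIPAIPRFKDLEPMEQFIAQVDLC
VDCTTGCLKGLANVQCSDLLKKWLPQRCATFASKIQGQVDKIKGAGGD
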