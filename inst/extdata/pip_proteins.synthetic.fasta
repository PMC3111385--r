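>CcPIP4;1
HSKGSTGQDYSRTQSDNPGSLGNATHFNHPQKTPSVYLFVLFRIMSANWLGQKVIGYADANCNGTSSQGRTFGLLTALFG
STAVFQLWLFGPGEKYTDEEGAHEGATGGHSMETANKVSAFRVNPAVLTGFWAALTTTRSQWMWAWACVIWRFIPTSGGG
ANGSSVAFTDEIHHLIFTDSWSMMSILEMVMGQQAAHTETVSLWFFLMGAALMHWWVVSHFRPSKGENPADGCSKRWGEG
RGWTCGSVTFDTVPAWAPVGGEFLSWMLSAETGNALSDKTAGETV
>CcPIP4;2
HSKGSTGQSYSRTQSDNPGSLGNATHFNHPQKTPSVYLFVLFRIMSANWLGIKKIGYADANCNGTSSQGRTFGLLTALFG
STAVFQLWLFGLGEKYTDEEGKHQGATGGHSMETANKVSAFRVNPAVLTGFWAALTTTRSQWMWAWACVIWIFIPTSLGA
SNGSSVAFTDEIHSQIFTDSWSMMMILEMVMGQQAAHTENVSLWFFLMGAALMHWWVWSHFRPSKGENPADGCSKRWGEG
RGSTCGSVTFDTVPVWAPVGGEFLSWMTSAETGNALSDKTAGETV
>PpPIP1;1
HSKGSTGQDYSRTQKDNPGSLGNATHFDHPEKTPSVYLFVLFRIMRANWLGIQVIGYADCNGSQGRTFGLLTALFGSTAV
FQLWLFGLGEKYTDEEGAHQGATGGHSMETANKVSAFRVNPAVLTGFWIMLTTTRSQWMWAWACVIWRFIPTSGGGANGS
SVAFTDEIHHAIFTDSCSMMMILEMVMGQQAAHTENVSNWFFLMGAALMHWWVYSHFRPSKGENPADGTSKRWGEGRGST
CGSVTFDTVPVWAPVGGSFLSWGLSAETGNALSDKTAGETV
>PpPIP2;1
HSKGSTGQDYIRTGSDNPGSLGNATHFDHPEKTPSVYLFVLFRIMSANWLGIKVIGYADCNGSQGRTFGLLTALFGSTAD
FQLMLFGLGEKYTDLEGAHQGATGGHSMETANKVSAFRVNPAVLTGFWAALTTTRSQWMWAWACVIWRFIPTSGGGANGS
SVAFTDEIHHAIFTDSWSMMMILEMVMGQQAAHTENVSLLFFLMGAALMHWWWVSHFRPSKGENPADGTSKRWGEGRGST
CGSVTFDTVPVEAPVGGEFLKWGLSAETGNALSDKTAGETV
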