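"tree_id","site","species","elevation","dbh","height","crown_length","aspect","slope","multi_stem"
"SYN001","synthetic","synthetic",2419.6,15,5.4,3.2,187,38.8,FALSE
"SYN002","synthetic","synthetic",2283,14.5,7.9,4.8,292,35.8,FALSE
"SYN003","synthetic","synthetic",2448.4,14,7.2,4.3,116,36.4,FALSE
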