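uid	|	parent_uid	|	name	|	rank	|	sourceinfo	|	uniqname	|	flags
1087695	|		|	Procladius	|	genus	|	ncbi:191633,worms:156905,gbif:1449280	|		|	
5000000	|		|	Silvataxon	|	species	|	silva:AB0001	|		|	
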