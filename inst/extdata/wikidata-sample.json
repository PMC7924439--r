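[
{"id":"Q140","type":"item","claims":{"P31":[{"mainsnak":{"snaktype":"value","datavalue":{"value":{"id":"Q16521"}}},"rank":"normal"}],"P225":[{"mainsnak":{"snaktype":"value","datavalue":{"value":"Panthera leo"}},"rank":"normal"}],"P815":[{"mainsnak":{"snaktype":"value","datavalue":{"value":"183803"}},"rank":"normal"}]}},
{"id":"Q7247420","type":"item","claims":{"P31":[{"mainsnak":{"snaktype":"value","datavalue":{"value":{"id":"Q16521"}}},"rank":"normal"}],"P850":[{"mainsnak":{"snaktype":"value","datavalue":{"value":"156905"}},"rank":"normal"}],"P846":[{"mainsnak":{"snaktype":"value","datavalue":{"value":"1449280"}},"rank":"normal"}],"P685":[{"mainsnak":{"snaktype":"value","datavalue":{"value":"191633"}},"rank":"normal"}]}},
{"id":"Q42","type":"item","claims":{"P225":[{"mainsnak":{"snaktype":"value","datavalue":{"value":"Douglas Adams"}},"rank":"normal"}]}}
]
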