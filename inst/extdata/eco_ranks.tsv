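# Default support ranks for Evidence and Conclusion Ontology accessions.
# rank is one of: experimental, similarity, prediction, other.
eco	rank
ECO:0000006	experimental
ECO:0000269	experimental
ECO:0000314	experimental
ECO:0000315	experimental
ECO:0000316	experimental
ECO:0000353	experimental
ECO:0000247	similarity
ECO:0000250	similarity
ECO:0000266	similarity
ECO:0000044	similarity
ECO:0000255	prediction
ECO:0000501	prediction
ECO:0007669	prediction
ECO:0000303	other
ECO:0000305	other
ECO:0000204	other
ECO:0000000	other
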