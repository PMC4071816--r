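allele	host_gene	extein_annotation	new_allele	new_host_gene
cdc21-a	cdc21	Cell division control protein 21	FALSE	FALSE
cdc21-b	cdc21	Cell division control protein 21	FALSE	FALSE
cdc21-c	cdc21	Cell division control protein 21	FALSE	FALSE
polB-d	polB	DNA polymerase B1	FALSE	FALSE
polB-a	polB	DNA polymerase B1	FALSE	FALSE
polB-b	polB	DNA polymerase B1	FALSE	FALSE
polB-c	polB	DNA polymerase B1	FALSE	FALSE
pol-IIa	pol-II	DNA polymerase II large subunit	FALSE	FALSE
pol-IIb	pol-II	DNA polymerase II large subunit	TRUE	FALSE
dtd	dtd	Deoxycytadine triphosphate deaminase	TRUE	TRUE
gyrB	gyrB	DNA gyrase subunit B	FALSE	FALSE
helicase-b	helicase	ATP-dependent helicase	TRUE	FALSE
ligase	ligase	ATP-dependent DNA ligase I	TRUE	TRUE
rfc-a	rfc	Replication factor C small subunit	FALSE	FALSE
rfc-d	rfc	Replication factor C small subunit	TRUE	FALSE
rir1-l	rir1	Ribonucleoside-diphosphate reductase	TRUE	FALSE
rir1-k	rir1	Ribonucleoside-diphosphate reductase	FALSE	FALSE
rir1-b	rir1	Ribonucleoside-diphosphate reductase	FALSE	FALSE
rir1-g	rir1	Ribonucleoside-diphosphate reductase	FALSE	FALSE
rir1-m	rir1	Ribonucleoside-diphosphate reductase	TRUE	FALSE
rpolA	rpolA	DNA-directed RNA polymerase subunit A	FALSE	FALSE
udp	udp	UDP-glucose 6-dehydrogenase	FALSE	FALSE
topA	topA	DNA topoisomerase I	FALSE	FALSE
top6B	top6B	DNA topoisomerase VI subunit B	FALSE	FALSE
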