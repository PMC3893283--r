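family	example_taxon	source
Clupeidae	Sardinops	tank
Scombridae	Thunnus	tank
Coryphaenidae	Coryphaena	tank
Carangidae	Naucrates	tank
Hominidae	Homo	intake
Engraulidae	Engraulis	intake
Bovidae	Bos	intake
Suidae	Sus	intake
Phasianidae	Meleagris	feed
Mustelidae	Enhydra	intake
Canidae	Canis	intake
Salmonidae	Oncorhynchus	unknown
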