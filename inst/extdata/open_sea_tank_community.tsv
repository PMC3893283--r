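species	common_name	genus	family	class	group	count	biomass_kg	lowest_rank_detected
Coryphaena hippurus	Dolphinfish	Coryphaena	Coryphaenidae	Actinopterygii	Bony fish	6	84	Genus
Mola mola	Ocean sunfish	Mola	Molidae	Actinopterygii	Bony fish	1	1000	No detect
Naucrates doctor	Pilot fish	Naucrates	Carangidae	Actinopterygii	Bony fish	17	12.75	Family
Sarda chiliensis	Pacific bonito	Sarda	Scombridae	Actinopterygii	Bony fish	15	45	Family
Sardinops sagax	Sardine	Sardinops	Clupeidae	Actinopterygii	Bony fish	13000	2600	Genus
Scomber japonicus	Chub mackerel	Scomber	Scombridae	Actinopterygii	Bony fish	17	7.7	Genus
Thunnus albacares	Yellowfin tuna	Thunnus	Scombridae	Actinopterygii	Bony fish	11	748	Genus
Thunnus orientalis	Pacific bluefin tuna	Thunnus	Scombridae	Actinopterygii	Bony fish	7	1890	Genus
Carcharhinus plumbeus	Sandbar shark	Carcharhinus	Carcharhinidae	Chondrichthyes	Cartilaginous fish	1	65	No detect
Dasyatis violacea	Pelagic stingray	Dasyatis	Dasyatidae	Chondrichthyes	Cartilaginous fish	2	5	No detect
Sphyrna lewini	Hammerhead shark	Sphyrna	Sphyrnidae	Chondrichthyes	Cartilaginous fish	2	109	No detect
Chelonia mydas	Green sea turtle	Chelonia	Cheloniidae	Reptilia	Turtle	2	258	No detect
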