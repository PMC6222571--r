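gene_id	annotation	chrom	start	end
GRMZM2G387394	Transferase	1	300173138	300174772
GRMZM2G341253	Malonyl-CoA:anthocyanin 5-O-glucoside-6'''-O-malonyltransferase-like	2	165106367	165108162
GRMZM2G075513	Anthocyanin 5-aromatic acyltransferase	4	170843898	170845760
GRMZM2G316787	Malonyl-CoA:anthocyanidin 5-O-glucoside-6'''-O-malonyltransferase-like	4	174072855	174074677
GRMZM2G382785	HXXXD-type acyltransferase	5	50372211	50374054
GRMZM2G436404	HXXXD-type acyltransferase	6	19122956	19124662
GRMZM2G095340	Anthocyanidin 3-O-glucoside 6''-O-acyltransferase-like	6	72337117	72341167
GRMZM5G800407	Transferase family protein	10	142328397	142330129
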