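>syn_aat_full synthetic acyltransferase-like sequence carrying all three BAHD motifs
MAATSVLEKHLPLDAVSERTPKNYFGNCLVDQAIGRALSEVLTHYPHLAGRLVTDENGDR
EIHCNDEGVLFVEAHADVTLDDLGDFAPSPEFRKLVPSVDYSKEAISEVPLLLAQVTRFK
CGGVSLGVGWAHILGDGWGAMQFLNSWAELARGEKAPSLPPVWDRELLSARSPPQVTFPH
SEYMPLEEMSSMSERYVSERFVFDGAAISALKARATGEGVPHPTRVEALSALVWRSAMRA
SRSVHGHLRPSLLVHAVNLRPRTVPPLPETSFGNLLSMAVTQASASDLLHDSLSHAVGLV
RRSIAEVTGDYFHELQGDDGFEACMRCFNEVSDFFEPDLYISSWTKLGFYDVDFGWGRPS
RVSLPEGPFGNSIVLMDTRSGDGIEALVSLDEAHMALFEKDEELLAYASLNPSVLA
>syn_aat_leu synthetic variant with the leucine form of the anthocyanin motif
MGSHKVEVVESTMVRPAAETPQRSLWLSNLDLLQARTHTPTVYFYRHDGSADFFDAAVLK
EALSRALVPFYPMAGRLARDEDGRIEIDCNAEGVLFVVAESDSTLDDFGDFTPSLELRRL
IPTVDYSAGISSYPLLVLQVTYFKCGGVSLGVGMQHHVADGFSGLHFINTWSDLARGLSV
AIPPFIDRTLLRARNPPTPAFDHVEYHPPPSLISSQPQPEATAKSATTSAILKLTPEQLG
QLKSKANNEGSTYEILAAHIWRCACKARGLPDDQPTKLYIATDGRSRLNPPLPNAYLGNC
IFTATPIAKSGDLTSESLSDTVKRIHNELARMDDEYLRSAIDHTESVRDISRLEAGAHTF
RCPNLWVISWVWLPIYEADFGWGRPIFMGPGGIAYEGLAFVLPSANGDGSLSVAIALQAE
HMELFRRFFYDF
>syn_trp_variant synthetic negative control with tryptophan at the variable motif position
MDALSKTSVAVEHHAAKLVKPSAPTPSHLRTYKLSLLDQLAPAAYWGNCIFFYAADAGFE
GAARVIEESLSRALVPFYPLAGRLGRDADGRLQVECTGEGAWFVEAAADCTLEDVNGLDH
PLMIPEDDLLPDAAPGVDPLDLPLMMQVTEFACGGFVVGLISVHTMADGLGAGQFINAVG
DMARGLDRLSVAPVWRRDLLRPEDPPRVTFEHREYDEVEDMSGTAGAASNSEEMLVHSFF
FGPAEMGALRARVPAHLRRCTTFEVLAGHVWRSWARALDLPEDQVLKLLFSVNGRGRFEP
PLPPGYSGNAVLPVTVVLLGELLERPLGYAVELVQKAKARVTEEYLRSVIDFLELQPDIS
ALVRGPTYFASPNLNINSWTRLPVHESDFGWGRPVHMGPACILYEGTVYVIPSPDSKDRS
LFVAISLPPAAMEPFAELFHHEMLQAGSASA
>syn_no_motifs synthetic control lacking every motif
MSTAEQKRVGGSSAARAPELVSKLSPEEQVRQASAMSLLESGKVTPMQAVESPARVGSAT
PEPTRVPAVEAVSMSAKELKELRDTASKSEQVPSVRSTTAPKEPVSSATESSVRQAPKES
>syn_unknown_x synthetic sequence where the fixed motif positions are unknown residues
MKTLLVASXYXGNCAPLWDXGWGXSERTVAAHKKXDLLPQRSTEVNAAGGSDEPRKLMMV
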