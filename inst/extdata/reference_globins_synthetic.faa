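>ref_fhb_syn
ELFTGVIVSPHFGQKDNGKLFMGTYNLETYHVLISYGNDHKFGVEGAYQALKTEKTTLTI
NQSVQFLILMGYCPPVFGTHKQLCLMVHDLKLSAGPEGLPALEPFVLLTWALFRRCKIVD
EQLIGNVSFLTYGVIPSYMTPEENNSGCVLHLEEDLAEPQIHLHRYRGNLLVVAVAYPAE
EVQDHTHRAILSAASFKPDGRDQNTVLFGATGIAGFKLFNWRFSPLGGNMGHDAYVEKDK
RLALGALKGKEVEVLLLVTNILGHLKSQMLGDVEEGGLRSHDSYFPALLLALADGPFYML
GKSKKVRAGLAAAGQLDNDNQDAYYYGVITIGFPESETIEEPNDMPVKADDGGLVHLTDQ
LIKEDTLDVTIMAGVSSEQALGAGELLVLLTTNNLKRDCD
>ref_sdgb_syn
ELFTGVIVQIRFFTKDNGKLFMGKHELESYKVAASYMNFYWFRVECKYQASSCFKNTSTI
NQDWPFLVRMGYIPPVLGTHTQQCMCVHALTYFAGPEGLLALEPFQLLQWSLIRRCRSPD
EAAIGNISDLTEGQWSSYETY
>ref_gcs_syn
ELFTGLIIDGDFFVKDNEWLFMGWCNLEEYKVAAMVWNLYKFFEEGLYEILKTFKNTSTI
NQDWKYLVRMYYIPDVLGTQFQQCQMQHNLTLFPGPYGLLALPPFVLLQEALIRRCRSVD
EDLIGAPSTLTYGVIIPYKAVRWGQHLDTKAFHGVDDDAGGTLVGLTKGDTIMVNESPQQ
FALKGQNLEIVGSIAAQIPMIRFERAPVVAPGSLLILRADFMMSIDKILGALIPLGEAVY
SAYDMDVYMGTSHVDLSAFAGGFKFKGKDGETIRRLPIHKESDKLPKLKEKFEEFEVALG
HSNGSARLRTQDGLAKLLRIGTPAAPESFDVRFVQEQQDNYDFSNKLMLYPAIIEIYKNE
FTQFYARNYDADQEQIDLLFDNGKAIMTTVCAGATVQINIGQQSGIVEGGIDETLMFYVG
SDTGIRVQVQKGFDESTNDECDIVKANEPVENEVLEEALLDEHMAKFAKTGCMLHHFLLK
AVYPNVKIEDQIGTLVAVIAEAFVWIVMES
>ref_protoglobin_syn
SEFLKRRECVRAAAEYLGKPLQMTAKKPSLCLGTMTEEFLDAVVCRKPYGIKLQGDLPTY
VIVGNRKFYYDDGILDMGTSGIERYEVECSYGNDYKFQMEGFGQALKTFKNTLEIGQDWD
ALFRMVYIYPVLFTCTAQLLMVHAGFKFSNEEGLLNLKPFVPVIWCCIRSCRYVDRAGYQ
NCITGTPIVIHSYPTY
>ref_ssdgb_syn
EVFTCVIVAIRFFKVDNGKMMMGTSNLIEYAGAAKSGNLYKFKDEGSNQALKSFDNTSTH
NQDWPIGVRISYIMPVNCTHQSQRWRGHALTYFAGIEGLLAPECFVLKSWAGNRRCGSWD
EALIGNMSTHTVPVIFATKTQ
>ref_thb1_syn
QMGPHGTLEADDHLGGQSRHTRMYWVRWDAFSRLCFNMGYQSGEDPHWGGLHGYKTRGPD
IVGCLSGAKEPASYTHSMLVHSKCAMCNNGVGSGTVEPKGPGLNKVNGVGSGKADMQAGG
TDVKLLVPFF
>ref_thb2_syn
VMVRNMTLKAKDMLGIHWRGTRIYRLRSDTMPSQRFWMVYQSPELGAGGGFHTYKTRGPN
PVGCLRGLKEPHGLHHSMLVSSIKAMANNGVGATAPNPTFYLALKVAIVGSGNIDIQARD
TDFKRETPFL
>ref_thb3_syn
GMDEAKTLTAKDMIGRHDYHTYNYWFLLDTCSCYCFNMSYQSKPLGAGGELHGYKDWHKD
GFGYVRAQKEYSELTHDMLVSSKKAMMCNGVGMGTFEPKSPGMLKHATVDIGPEDMNAGT
TSVKVNTPNL
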