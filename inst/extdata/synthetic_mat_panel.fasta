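>synthetic_STE3_alpha role=STE3 class=alpha
TDVGLKVSWLCSAFRMNVIVVRMEAAFQGPVFQIDSGQQPLLRPVASGSPDNCRRASPRL
SISADLRQLINGVSHGSCRRTRAHPLACRLTCLKRDCILRCGCGGQEDNPEDYDRLGKHI
LPSVQSIGQEQSMQQNIPAISCADEVSCIGQIADVAIIGFDKSYHAYGGLEIRLIIRTNA
CQFFRLVSRNAVLRHPYLLTTRISSSIPARASSRILLDVSIVKSPVMILGRLLLDPLLKK
KSPTVMSKAQAQWEDLRDGIAAIVCRYRTSSLAILASEYENPGTVRSNFPVQSSHLLCFE
ARGHLSGSDFTLHIALTVQMFAIMISGGGTRTSFDIRLRRVFQTRTRRSPRLIELLVVTW
TDIVNVASIATSENRRRIIPRRRSMMKREGQLGGPAAMPTCSATTLEAITQVFTDTPARI
QEIA
>synthetic_STE3_a role=STE3 class=a
MVSCLKVSCASVQLASLLRDAGGRLAQRSTVIQLENGSPTLLRLADSGASVHCRRHHPRL
SASVDLRRPAHGLSKGGWALTLEHPIASGVASLVRSRDQRVAFSVDDDNPGYYAGRDKRI
LPLDPSIRQKQFIQNNIPAFSWDAAVTCHDQRGGNAIIGPGERSHAHGGVAIRLLMIGDA
FMLTCLVLGNGARRPSSLPATLYSNPTPVRVWWRTLMNVCVANSQVHILEQLAIHIVVKG
KSPTTRCKGPPRWENYGDGIDAGDLGSVPLSLTEFALEEDSQGPTPYNVTIVSGHVLCLV
GGGHTSGSAACVHIALIVQVYTFLPGRESTGTSFCSKLLHMAKLGSFRHPRPMAIPTIIW
TGTFAAGPIATCTNRRCIFTKQRCMIERKERLGGPLAMALGPASIINRILHVLTDSPVRA
HEIA
>synthetic_SXI1_ref role=SXI1
MTLVKGSPFLASLKPSPPQGTRGSSPLSDKLVASGALTIRIIPLRQATQPLVVYSSETRI
DIKQIIRRIEISSRPSHGAGGHFQEPSDFGIGETRTLTVVHPSDGCPTPRLPRQETPRLQ
VEMRRSKYITTNLLLSIQHPEIILSYPSGLCEHAAISILSFHNDPASILRKFGAWQVPSR
ILLFLDWHLSRGSVPATCGRADVVHNPVSVTPQMLGSLNIKRAACALTLPRTSLHVSRRG
WEGELPDLAESTYFALFTMIRTVHVSTPCTGGIQPQFMVLRCRTIRRALHWQLMQLSVNS
AGVVGGVQFRTKRQSFRPHNPISRLWMPHGVTTGSLVLSWTRKVVPLFRTQVKWFAMELR
KIGSSRRRATFVAQESKSFGGLIDVASLVLSSDLFHDSR
>synthetic_SXI2_ref role=SXI2
IRSLALANPYDEPPHSKCSNEEEPIFKGSNACGTYKTKQPEPQGRRGTIYLRGLAISPHG
PYIAFLGGTPRGSVNRADSPWGPGNPGVRFVVVPDDFAPGGSAYLTLGIVRHCLKFPDYS
PGIARSVEPEYGLVSGSAEVPQAVQQGNAVHAVAVSSSVRSVAHFTHPTVASRLSARNVD
AEHLDQLRTVECPLTMGASGVALGCCVRIGPFRLDCNCAEVLLPACNYRFRRTANSSDFC
KRFVRPRGIRHLAALYDHKGNLKLYVFLRHVHALSVVPLSESSRSVCVYLGSLDDQTTLY
WVTKCRLIISKVPYRNAHPLKKNILPTAVRIRGPLSTFQTHTRFYPRPLRKDKMTVIRRP
TLSKLRGIERYRAIGSNHRPPPQTIGLGKEYGVTGGNSV
>synthetic_STE20_ref role=STE20
MPIMVPVASSCICTPLHRTPVRYFVENIPLTAVGPYEAARQDLTRGPLRTYEASSCSEGD
IPTRVRHIRRFRFGFDRGPTLAPWLLPIMGRTGKNCSYIMSKPEASLRQCSTAGIAPYFR
RCLNRSKRTHLRATISLVDRPRLISRELVGRLNPAQSAPMGVCMSIVPKLLTAARADIPR
PLESIMEQPASRSHAPRNSLRFTVEYVPGTDDCMDSGVKVRITMHVAIAAISFSHVGIQR
TFTQWGKCQPGGGQDGYFEDGSCVNLARKASSKGVVMACFKGNMIAPGIPSYEVSSDRCV
QIRNRGQCGEKCGRKKHPCRQHVWRRHTVSYVGIGNRVNLVDPVEGPRLISYLPAPLCVP
LARSVTICHVNLAERALQRWPTPRWLHRLLGYASERSLTHQMSIKPGDANLTSVLSYEHV
GGSICSILFIGEGTIRCAPAIQTILYDRIASSTHLSEAFIRVDRPSEDILGMTRYPRPLG
PGRNGPLVRILKRWSRLVLERGQSNASARACRAIRWRLGRHSCGVGAYCLRRVGISLVER
RNPRVVQAVYAAPQFPSCYRRGVHECAIDQYFEKLIQRNTVGSRHSLLKNSRNIKTLAQH
YTTPAVMPLPGEKRIAVLQRGDRASMRTEAGVLHRDVVTTIIVFITAKDMSSKYNDGIYV
VSFGRGYSRRIYQVHAPLPEQLGIATARVPLAYHGQLWK
>synthetic_IKS1_ref role=IKS1
MQRTSGPWHTRDLILKLNIKPVGRQPETATLCTRLRCSGAFWRNERNIAEKRWLMLSVRR
PSYRTATSERHHLSRYANMELRLAFTVVGSSHVYLALGLSYYALLTPYWPRSLVAVTIHV
PTDAQIQFRTKALLLVRTCLSPALFRHEGMTHAAPEDGLLAANLCRSPTHSSSTYNTHGL
VFSVCVPRPYDGQGSRCSASTSFVDLESLRPLAHPLLNGGSVGVHYSDAKAVLSASSHEF
ALHLVASDAPTRGVCIPRCRPSFRVAEFIPAVLTASVYLRPSRACATVRWAPHRKAIAPG
HFVPVDRGIRGQYVDIGSCMLTILESPPAHSVRHIAGPECLEVRVEYKNWPTDPIRENLC
GSRIIVQRDFLSPGPRCPRCDVSQFKDRILKAAVTNGYLRHPDIAGWSARRRVPCAWPRL
HLGSRSARRRNKEPINTLPHPLLRGRHIVPYRLLRDRNIMLREPIHFSGPWALYPALSDR
VLPFSDFPVAIRAQMRSLTPIELLLIDNSPCVVHVKTGLTQSRYGIEPNLSNLQRIATQY
LLRFTPQHFTARCVARFEPLGGHRTASSAYLVGGSGYVRAKRSFRLKSILYAVVRPVPA
>synthetic_STE11_ref role=STE11
MRRISTRVLVPHLSLFLRQGTRGLSNVGDRPLKAKDPYEACPRYLICVRGRLMRLVYNTA
AVSAIFRCCVKCFSCDIVGGHPVARRWSTLCRRRPVTLLLSAKQGNSLCNSGALNSRVRK
RGGELCANTIGGHPLASSTAQRTASHTLAALHGGGVLCPQARRSAILSLSTRKPVCRPTN
PRGVPSRSVFAYNVQGVPCAVRPHLEAELTKGREMYDRSYRPETTLASLGRYTTPGLYSL
RRRPQRATFVGGGPITVLLQLAPPIQILVRFPQWELICLHPDSFVLICVSLRTPLLHGSG
QHEAYGGRGAARLIMAASDRNSNELCLEGFFVRSTLLRQVEVANLRELTFPRLYIGRIPY
HYSALKVAGLRVAKSGAAPTSRAFRRDARQGQRINFTRSKLYERRLKAVESRTRTTIDRT
TQGFSLPCTLIIAGSYNVQVYSGWVLPSVLGRTDNCSVKRVNKMLQQKLYNPTHLLSLAD
GIDEVFDPLESKGLLLEPLRPLRHRGWQYVTWVSRLMLAASATHSSFKSDFGVTRNSLKM
RIRGAYFGKIRILPTPVLISLLTTSAPVSNAKQQRTLTSTQGQRKLGHSPIKSWPIGHCV
GLPRCCVGAPLGSPSTTSPGTVRYLGPDAIFEGTITILVLESTWVTVLSVAPRAEHTERG
HEFFR
>synthetic_MYO2_ref role=MYO2
MTLWADRVLARMSFHPVRKPQGTMTVADQRNTSTFTPGPVVNPRSFPIRTISLYTASTPR
VGPNSKTPACIVIYIHGEPLVMGRDPEGHCVPICMHVCELKLGLVQSINLVCSVIHEFGD
SVLSTDGCSNSQERSDSVHTRRGGSREGVMPELTDRSLSGHQQTYWSHYRPYQHTNQCGT
LAQGGLPFFKSARRYLYLLYISSPFGINIGWHLGTRLWVSEAAPARLRGTLPKVKNEQSL
SAPFRRQWHPLHGFRQVSLSGSSLLTESWPYAPIRRPLSWIELLLRLHVHGRIRGIISIG
LPISASTTVPFKPKGESRALRRSVDRVLGPWHGYPAHFLCLTGKTEMETPPRYNAALPDF
DGQPKPGYIRSPFRCVKGLWTGTVGWLYVRCGFPSGTCSHRTNEAYSGYGLGTGGAVAPC
TSGCISFASTECAINDAGLGSQGEELGTTDKRFEFSFSRPFARHTELTGGILTNEIHTTG
RRSVAGIQSHHHLGSGAETPPECSGGPWEVYKMEWSIVDASSFRSSVYTLVPSDSLATRL
YGGRLVLSEHKVVYVVLTFLDLTPAIMAEFLIRPVGGACKGNPRQIRGRGQVSYRSDIVK
FPTPQLVQTWFPQGVGCWGGSLASRWIQQENIWKPGLQTSGLGGDSRGRANLSYRISSNM
QPSVRMLNVSLATSSRNGRHMSRVRQPSRCCTWKMSQGPGSERVTQLHNCGSTGSTHSLL
SCKVLAKKKATIISAKGAISPEVAGFRLRLISLALIHGPTTDGDEDRLQYRNHQVPPRRT
ALTAHACISSSTSELRVGP
>synthetic_RPL22_ref role=RPL22
MEGRFRGGRTAAEARTWGLGPPASLIRSTTFCYTIEIGTQTRLRPSHPSATREILDVRNS
GGLPVFEKLRFVAHQSGSHARRRQRSFDADVIRAGVFEGPSAGTQQLTPAYLDRDKRRSQ
PSTDSVLLHVYGVAAGGYTVNLSPFYKKATPAGKARHKISECSQRMHSHPPVRAAKPVDA
CLTGYGFACHPSNIGWIVSCRNSFLRSEVTAEVTDSVHSLLIPRCTEWARYLRLSNLLIP
AKQSANVYKRGASAVSVYQGCISVTFWQKPHGKEHPTHWPPGRFWLASATLRRDGMDFW
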