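>pflB_ref01 synthetic seed-alignment member
AECIASQVQNTLLIPKFHYHGYIEGLTKRYMVR-NEITSRATTLATGLWKFCYQNRAEID-MREHKDVSPLIKIEESPAT-ADTQTQPIGQLGFLTDETTYSSTKGCSANQRVQFLILEKTAKRLILDAADKENTDIAA-LH-KLPLFKKAIKVDRGHSQQHCTVGDYYHLTDIDSQNAQ-INYKASNRRGRLAGDTTKLAAMSADVCKAVQLTQTHVLWAEVLSDIKHRVMPEYPPDRVLESALA-NGFT-SPRMASTFCISGDEVHPIGIMCQIEPVFAVDVDMKADE-KITYGDAEQYFQQGRFALNVASTERPTRMGRTFMQMYALKSLATTKRLENYLVKWFEDQKQVTLAEIDGFTDKAPSLMVRF-AYHLSIDQSIGKCQGLDLTMKTRIRFENGENVASENDDNPPCKQEEPTNGTVYTKRGFRHENLLCNCQQGGEKKDYKPKTYLYSLVSSFSLWIYFCYHAGFPVQHTS-CMPKAFTLLPKTIARAECDRHMTFDLLTYPQEARDLGSSDEFATLGGFIGQLTVDKRGITNTLAVSGEVN-REEEQ-NRQHGMPSSLARIYATIADEDG-VPDCQLEVILLHTSSINSRPFADDMTIILTGAGVNPVTV-CIEGKQPPKEMFASPAYGANFHVVFWRDNADQIFCSNLTGNRPKTRRSKTILNVEFVIRSAKEASICCNAKSKLKAFFEATGNPGDTAVDLKEQELGPNVIEKYENPDLELYFFAGLSF
>pflB_ref02 synthetic seed-alignment member
AESIASEVQNTLLICIFVYVGYIEGLTKRYMVRGGEITSRATFLALGYWKFYYNNRYEIWSTRERKDMSPLIKIEESPAHLADTQTAPIGQLGILNDETTYSSTTMFSACQRVQPLILEKTAKRLRLDADPKENTDIAAATHLKLPLFKKAIKDDRGASEQACTVGDYYHLTDIASQEAQQCGYNGSNRRGRRAGDTQHLAFDSADVCKDVQLTQTHTFWAEGLSDIKHGVMPEYLPDRVLESASAHNGFTASPAMDSTFCISEDEILPIGHMCQIEPVAAVPVDMKADEVKITWGDAEQEFQQGRFALNVASGEKRTRVARTHGQMYALKSLATTKVLENYLVSWFEDQKQVTLACIMGFREKALQLMVRFAAYGLSDAESIGMTMGHDRTEYTRIRFENGENVASENVTNNPQKQVEQTNGEVYTKRKFRHENLLCNTQQGGEKKSNKPKTYLYSLVSSFDLWIVFIYHASHPVQITTICMPKAGTLLPKTIQHAECDRHEGFDLLTYPQEARDDGSSDEFATQGGGIGQLSVDESKGTNTKAVSGEVNNRKELGQNQQEGMPSSLARLYATIADFDGEVPACQVEVILCHTSSINSNPFALDMEIIKTGAGPNPVQVANIEGKQTEKEMFAAPANGANFYMVGWRENADQIFCSNLTKERPKTRRSKTILVEKVVGRSDKEASICCNAKSKLKLFFEATGNNGDTAGDVVEQEPGPQVIEKYENPDLELYFAAGLSL
>pflB_ref03 synthetic seed-alignment member
AECDMSQKQNFLAICKIVYAGYIEGLYKRYMVRGDEITSRAAFLALGLWKFYYNNRHEIGSPRERKDVSPLIKIEESPATLADTQTAPIGALNFLNKETTYSSTMGPSACQRVQFLILEKTAKRLILLALCKENTDIAAALHLKLPLFKKAQKVDTGASEQACTSGDYYHLTDIDSQYAQQINYNGSNRRGRLAGQTTKLAADSAAICKAVQLTQTHTFWQEVNSDIKHGVMPEYLPDMVLESASAHNGFTNSPAMDSTFCISADEIHPIGIMCQEEPVAFVPVDMKADEVQITYGDAEQEKQQGEFALNVASWEKRTRVARTGMQMYAVKSLATTKRLENYLVKWFEDQKQVTLAEIVGFTDKAPQLHVRMAAYGLSDHESIGKCYGLDDTEKTVIRFMNGENVASENDRNNPCKQEEQTNGTWYTKRGFRHEQLLCNTQQGGEKKSHFPKTYLYSVVSSFSLWIYFIYHAGIPVQIFSICMPKAFTLLPKTIPGAEEDRHLTFDLLTYPQEARDAGSSDEFATVMGGIGQLTVDKRQITNTLAVSGEVNNKKHLGQNGQAGMPSSLARILPTAADEDMEVPAKQLEVILLHTSSINSRPDADMMTIILTGAGPNPVTEANIEGAQTPDEMFAAPAYGANFHMIGWRENADDDFCSNNTGERCKTRRGITILNEKVVGCSDKEASIKRNAKSKLKLFFEATGNPGDTAGDVQEQEPEPAVIESYELPDLELTFEYRLSF
>pflB_ref04 synthetic seed-alignment member
AFCIASQVQNTLLICKFVYVGYIEMLTKRYHRR-GEITSRATFLALGLWKFYYNNRYEIG-MRERKDVSPLIKIEESPAT-ADTQTAPIGQLGFLNDELTYKSTKGFSACQRVQFLAGHKTAKRLILDAADKENTDIAA-LH-KLPLFCKAFKVDRAAHEQACMVGDYYHLTEIDSTYAQ-INYNGSNRRGRLADDTTKLAADSADVCKAVQLTQTVTSWAEVLSDIKHGVSPEYLPDRVLESASA-YTFT-APAMDSTFCISADEIHPITIDCGGEPVAAVPVEMKADE-KITYGDAEQEFRQGRFALNVASGEKNTRVARTFMQMYALISLATTKGLENYLPPWFEYQKQVTLAEIVGFTDKVPQLMVRF-AYGLSDAESIGKTQGLGPTTTTRIRFENGENVAEENDTNNPCKQEEQTNGTVYTKRGFTHENMLCNCQQGGEKKSIKWKTYLYSLVSSASLWIYFQYHQGIPVQITS-CMLKAFTWLPCTINWASCDRKETFDLLTYPQEARHILSSDDGATLFGGIFQLTVDKRKWTNTLAVSGHVN-RKELG-NRQAHMPSSEARGYATIADEPG-VPMCFRLVILLQTSSMNSYPFADDRTIGLTGAGPNPNTV-NIELKQTPKIMFAAFNYGANFHMVGWRENADQIFKCNTTGEMPKTRRSKTILNEKVMGRSDKCASICCNAKSKLKLPFEAWGNPGDTACDVQEQEPGPAVIEKYENPDLELYFFAGLSF
>pflB_ref05 synthetic seed-alignment member
AERIASQVQNTLLWCKFVYVGYIPGLTKRYMVRGGEITSRATFLALGLWKEYINNRYEIGSMRERKDVCPLIKIEESFATLADTQTAPIGQLGFLNDETTYSSTKGFSACQRVQFLILEKAAKRLILDAADKENTDIAAALHLKLPLFKKADKVDRGASEQLCTVGDYCILTDIWSPYAQQISYNWSNRRGRLSGDTTKLDADSADTCKAVQLTQTHTFWAEVLSEIKHGFMPEYLPDRVLESAPAHNGFTNSPAMDSTFCISADEIHPIGIMCIIEPVAAVPVDFKADEVKIEYGDAEQEFQQGWFNLNVQSGEKRTRVARTFMQMYALKSLATTKRLENCLRKWFENQKIVTLAEIVGTQDKAPQLMCRTACYGLHDAESIGKTQGQDPTEKTRMRFENGENVSPENDTNNPCKQEEQTNGTKPTKRGFRHENLLCNLQQGGEKKIIKPKTYLYSLVSYFSLWHYFIYHMGIPVQIGSICMPKAMTLLPDTINWAECDRHETFDLLTYAQEARDLGSSDEFATLGGGIGQLPVDKLKNTNTLAVSGEVNNRKELGQNGQAGMPSSLGRIYATIADEDGEVPACQLEYILLHTHSIASRNFADPMTIIETTAGPNFVTVANIEGKQKQKETFAAPAYPANFAMVGWCENADQIFTSNLTGESPKWRRSKTILQEKVVCRSDKEACFCCHAKSKAMLFFEATGNWGDTKGDEKEQEPGPAVIEHYENPDLELYFRAILQF
>pflB_ref06 synthetic seed-alignment member
AECIASQVQNTAVICKFVYVGRIEGLTKRYMVRGGEITSRATFLALHLWKCYYNNRYEIGRRRERKDVSHLICIEESPAGLADTQTAYIMQLGFLNDETTYSSTMGFSACQWVQFLIREKTGKRLILENGDKFNTKIYAALHKKLPLFKKAIKVDRGASWQACTVGDYYHFTDIDSQDAQQHNYNGWNRRGRLAGDTTVLAHDSARVCKAVQLTQTHTFWAEVLSDWKHGVDREYLPDRVLESASKSNGFTNSPAMDSNFCISADEIHPIGIMCQIEPVAAVPVDMKADEVKITYGLADQQFQQGRFALNVASAEKRTRVAITAMQMGALRSMATTKRLQNYLVKWFESQKQPTLAEIVGFTDKAPQLMVRFAAYGLSDAESIGKYWGLGPTEKTRIRFENGENVASENDTNEPCKQEEQTNGTYYTKRGFRHENLLCNTQQGGEKKSIKPKTYLYSLVSSFYLWIHFVYHAGIPVQITSICMPKAFTLLPKTINWSEMDRKCRFDLLTYPQSARDLESSDEFATLGGIIGQLTVDKRKITNTLAVSGEVNNRKELGQNFQAGMPKSLAKKYATIADEEGEVRACQLEVILLHTSSINPRNFADDMTIILTGIGTNFVTVANIEGKQTPKEMFAAPAYCQVSHPVGWRENAHQIFCSNLQGERPKTRSSKTILNEKVVGRSDKEASICCNAPSKLKLFFEATGNPGDTCGDVQETEPGPAHIDKYENPDLELYFFAGLSF
>pflB_ref07 synthetic seed-alignment member
QECIAGQVQNILLICKFVSVWYNEGLTKRYMVRNGEITSRATFLALGMWKFYYNNRYEARSMRERKDVSPLIKIEESPATLADTQTAPIGQLGFLGDLTTYSSTKGFSACQRVQFMILEKTAKLLILDAAPCENTDIAAALHLKLPLFGKFFKPDRGASEQWCTVGDYYHLTDIDSQYAQQINYNGSNRRGALAGDTTKLAADSADCCKAVQLTQQHTFMAEVLSDIKHGVMPEYLLDRVLESASAYNGFTNSPAMDSTFLPSADEIHPIGRMCQNEPVAAVPVDNMALEVKITYNDAFQEFQQGRFAVNVASGEKRTRVARTFMQMYALKSAATTKRLEWYLVKWFEDQKQVQGAEIRGFTDKAPCLMVHFAAYGLSDAESIGKTQGHDPTEKTRIRFENGTNVASENDTNNPVKQWEQTNGMVYFKRGFRHESLLCNTQQGGEKKWIKPKTYWYSLFSSFSLWIVFIYHAGIHVQLTSICMPYAFTLLPITDNWAELDRHEMFDLLTVPQEARWLGSSDEFATLDWGIGQLTVDKREITNTLAVSMEVNNRKELEQNGQAGMPSSLNRIYWTCADEPGEVNACQLEVILLHTSSILSRPFADDMAIILTGAGPNPATVANIEGKQPPKEMFAAPASGANFHMVVWRENADQIFCSNLTGERPKTRRGKTILNEGVVGRSDKEASICCWAKSKLKLFFEATENPGDTAGDVNEQEPGLPVIEVYENPNLELYFFAGLSF
>pflB_ref08 synthetic seed-alignment member
AECIASQVINTLLICKFVYVGYIEGLKKRYMVQ-NEIQRRASFLMLGLWKFYYYNRSEIG-MRERKDVSPLIKIEESPAT-CDTQTAPIGRLGFLHDETTYSSTLGFSACQRVQFLRLDKTAKRLILDAADKYNTDIAA-LH-KLPLFKKAIKVDRGASEQACTVGDYYHLTDIDSQSAQ-INYNGSNRHGRLAGDTTKLAADSKDVCKASQLTQTHTCWAEWQSDIKHGVDPHYLPDRVFESASA-NGFT-SPAMDSTFCISADMIHEYGIMCQIEWVAPVPVDMKADE-KITYSDAEQEFEQGRFALPVASFEKRTRVARTFMQMYALKSLATPWGLEWYSVHWFEDQKQVTLAEIVGKTDKAPQLMVRF-AYGLSDAESIGKTQGLDPTELQRIRFENGENHASENDTMNTCKQEEFTNGKVYTKRGPMHEHLMCNTAMGNEKKVIKIKTYLYSLVSSFSLWIYFIYHAGINVQVTG-CMPKAFTLLPKTINWAECDRHETFDLLTYPQEARDLGSSDEFATLGGGITQLTVGKREMTNTLAVSGEVN-RKELG-NGQAGMPSSRAYICATIADEDG-VPACQLEVILVHTSSINSMCFGDDMTIILTGAGPNPVWV-NIEGKQTPKEMFAAPAYGGNFHMVGCQENADQIGCSRLTGERSKTRRSKQIENEKVVGRSDKEAQICCNGKSKLKLFFEATGNPLDVAGDVQEQEPGPAVIEKYENPDLELYFFAGLYF
>pflB_ref09 synthetic seed-alignment member
AECIASQSQNTLLICKFVYVGYIEGLTKRYMVRGGEDTSWATFLALGLWKFYYNNRYEIGSMIERKDLSPLHKILESPATLADTQTEPQGQLGFLGDETTYSSTKGFSACQRVQFLILEKLAKRLILDAAIKENTDIAAALHLKLPLFKKAIKIDRGANEQACTVGDLYHLTDIDSQYAQQINYNGSNRRGRLCMKTTSLAADSADRCKAVQLTQTHTFWAENLSDIKHGVIPEYLPDRVLENAKFHNGWTNGPAMTSTFCISPDGIHPIGIMCQIEPCKAVPVDMKADEVKITPGDAEQTFQQGRFALNQASGWERTRVARTFMQMYDLKSLANTKRLGNYLVKWFEDQKSVTLAEIVWRTDKSKQLMVRFRAYQLSDAESIINTTGLDPTEKRRIRFEDGENVASNNDTNNPGKQEEQANGEFYTKRGFRHEGCLCITQQGGEKKSIKPKTYLYSLVSSFSLWIYFIYHAGGPVQITSITMPKFCTLLPKTINWAIEDRHEDFDLLTYPQEARELGSSDEFATLGGGIIQLTVDKRKITHTLAVSEEVNNRKELGQNGQAGYFSSYARIYATIADEDGEVPACQLEVILLHYSKINSRPFADDMTIILTGAGPNPVTVNNIEGKQTPKEMFAAPAYGANFHAVGWRSNADQIFCSNLTGVRPKTRRSKTILNEKVGGRADKMASHCCNAKSRLKLAFEATGNPGDTAGDVQSQEPGPAVIEKYENPDLELYFFSGLSP
>pflB_ref10 synthetic seed-alignment member
AECIASQVQETQLICKEVYVGYIEGWTKRYMVRGGEITNRAWFLALGLWKFYYNNRYEIGSMRERKDVSPWIKIEYSPATLADTQTAPIGQLGFLNDMTTYSSTKGFSACQAVQFLILEKTAKRLIFDAADKCNVDIAAAHVLKLPLFKKAIKVDRGASEQACTVKHWYHLTDGDSQYAQQIEYNGSKRRWRLAGDTTKLAACSADVDKAVQLNQTHIFWAEVLSMVDHGFMPEYLWDRVVESASAHTGFTNSPAMDSTFCISADEIHPIGIMCQIEWVAAVKVDMKADEVFDTAHDNEQVFQQIRFQHNVESGEKRTRVARTFMQMYALKSLATGKELENYLVDWFRDQKQVTLAEIVGFFDKPPQLMVTFKASGLSDAESIGKTQALDPTEKTRIRFENYENVASQNDTNNPCKQEEQTNRTVYTSRGFRHENLLCNTQQGGEKYSIKMVTYLYSLVSAFSLWIYFIYHAGIPVQITIICMPKAFTLLPKTINIASCDRHETFDHLTYPQEAYDLGSSDEFATLGWHIGQLTVDKRKLTNTLMVSGEINDRKSLGQPGQAGMPSSLARIYATIAGEDGEVPACQLEVILLNTSSINSRPFADDMTHILTGAGPNPVTVANIEGKQTPKEMFAAPAYGANIHMAGWRENADQIFCYNLTGERPKTRRSKCIKNEKSVGRSDKEISICCSAKSKLKLFFEATGCPGDTAGDVLEQEPGPAVIEKYENPDLELYFFAGLSF
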