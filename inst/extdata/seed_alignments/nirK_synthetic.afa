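>nirK_ref01 synthetic seed-alignment member
GYATYGSPLDIKQQGISKVGMKNPLGCESQLSADLIQIIIVMLMTRLLCKLANAAQNEQDASKGMEPDEMIGGKRYPEGAAHLMMGELEFSEADAGLILHECRAMLTLEVVAKWHKTESIDGATRPVGNQAAIVTAVKGDYGDFKNLECTGDLNMEYRLAMNAEKKSFGGSQLDADGQDDGGQKTIAGMDTDNYKHPDVSGLGSEPLQLPAYKLKPLGSNFFSWSYAGQFVSFGAGTLFFPFIQCWETINIADFEMRATERGDEDIDRAFATSFMPKRCMNGEANKNAKEQLDVTERGNSTPSGAYPHTPLGVEVLSVLPDIMIMELNGICWRHEFLLVD
>nirK_ref02 synthetic seed-alignment member
MYATYGSPLWISTQGINKVGIKNPLGCLVQLSADLIQIIIVMRMTRVLCKLANAAQAEQDASCVMEPDEMIGGKRYTEGAAHLMNGESEVSERDQGLILAVCRAMLTLVVVAKWHAGESVDGATRPTGNQPAIVSAVKGDYQGFKNLECTGTLNMEPHLAMNFEKKSFQGSQLDADGIDDGGQYTIAQMDHDNYKHPDVSGLQSEPLKGPAKKLKPLKANFFSWSIAGQFVSVGAGMIFFGFIQCSETINAVDFELMATDRGAELINLAFATSMMPKRYMFGYANKIAYETLDLTERRNSTPSGAYPHTYLGVELLSVANDIMIMELNQICIVLEFLLFD
>nirK_ref03 synthetic seed-alignment member
GYATYGSPLDIYQQGISKVGMKNPLGCESQLSADLIQIRIVMRMTRVLCKLANAAQQEQDTSKGMEPDEMIGMKRYTEGAAHLMNGELETSENDAGLILAECLAMLTLTVVAKWHKGESIDGANRPKGNQAAIVPAVKGKVQDFKNLETSGTLNMEERLAMNAEKKTFQGSQLDALGIDDGGQKTIAQMDTDNYMHPDVSGLQSEPLQGPAYKLKPLKANFFGWSYAGQIVSPQATTLFFPFIQCSDTINAVDSELRSTDRGDIDIGWIFAASMMPKRCMNGFANKNAKETSDDTEYRNSTPSGAYPNVYLGAELLSVAKDIMIMELNFICEVLEFILFD
>nirK_ref04 synthetic seed-alignment member
IYATYMSP-DISEQGISKVAMKNPLGCESQLSAILIQIIIVMRMTRVLCKLANA-QNEQDASKGMETDEMINGKRYTEGAAHLMNGELEVSEADA-LILAECRAMTTLVVVAKWHKGEEIDY-TRPKGNQAACTSHVKGDYFDFGNLECTGTLNMYPRLAMNAEDKSFQNSQLDADGIMDGGQKTIAQMDTDNYKHPDVSGFQSQPLQGLAYKLKPYKANFFSWSYAGQFVFVGAGTLFFPQAQCCETINAVDFAMIDRDRGDEDIGEAP-TSMMP-RCMQG-ANKNGKEGLDDTYRRNSTPSGAYPHTYLIMELLSVLNDIMIMELNQICWVLEFLKFD
>nirK_ref05 synthetic seed-alignment member
GYATYGMPLDISQRGISKVKMKNPLGCESQLSADLIQIIIVMRMTKVLCKLANAAQHEQDASKGMEFDEMIMGKRYTEGAAHLMNFELEVSEADAGLILAECRDMLTLVVVAKWHWGISIDGATRPKGNQAVIVSAVKGDYQDFKNLECTGTLLMEPRLAMNRNKKSFQGSQLDADGIDDGGQKTIAQIDTDHYYHPDVTGLRSEPWQGPAYKLKPIKANFFSMSYAGSFVSVGAGTLFFPAIHVSETINAVLFELRATLRGDEDPGEAFATSMIPKRCMNGEAEENAKETLDDLERRNSTPSMIYPHTYLGVEGLSGNNDIMIMELNQICWVLGFLLTD
>nirK_ref06 synthetic seed-alignment member
GYATYCSP-DIRQQGISKVGMKNMLGCESQLHADLIQIGIVMRKTRVQCKLANA-QNEQFASKGMEIDEMIGGKRYTEGAAHIDNGEGEVSEADG-LILAECRAMLTLVVVATWHTGESRDE-TRPKGNQAAIHSAVKGMYQDSKNLECTGTLNMWPRLAMNEEKKSGQMSQLDADGIFDGGQKNIAQMDTGNYKHPDVPGLQSEPLQGPAYKLKPLKSNFFSWSYAGQFASVAAGTLFFPFIQCSETINAVDFELGRTDRGDEDIGELF-TSIMP-RCMNG-ANKNAKETEDGTGRRNSTPSGAYPHRYLGVELLSVANDIMIMELNQIMWVLEFLLFD
>nirK_ref07 synthetic seed-alignment member
GYATYGSP-DICQQGCSKVGMKNPLGCESQLSRNLIQIIINMRMTDVDMKLAYA-QNEQDASKGMEPDWCIGGKIYTDGAAHLMNGELEVSEADA-LILAECREMLTLVVTAKWHKGESLDG-TRPKGNQAAIVSLVKMDYQDFKNLECTGTLNMEPRLAMNAEKKSFQGSQLDADGIDDGGQNTILQMDTDNRKRPDVMGLQSEPLQGPAYKLKPLKVNFFSWSYPGQFVSVGNGTLFFPFILCSEDINAVDFELRATDRKDEDIGEAH-TSMMP-LCMNG-ANKNAKFTLDDGERDNSTNSEAYPHTYLGWELLVVMNDIMIMELNQICWVLEFLLFH
>nirK_ref08 synthetic seed-alignment member
GYATYGSPLDISQQGISKVGMKNSLKCESQLSADLIQIIIVMRMTRVLCKLAWAHQNEQDAYKGMEPDEMGWNRRYTEGAAHFMNGELEVSEADAGPIHYPCRAMLTLYVVAKWHKGESADGATRQKGNQAAIVSAVKGDYQDFKLLEETGWLNMEPRLAMNAEKKSFQGSQLDADGIDDGGQKTGKQMDTDNYKSPDRSGLETEPLQGPAYKLLPLKADFFSWGYAGQFVSVGWCTLWFPFIQCSEVISAVDFELRATDRGDEVIGEAFAGSDMTKRCMNGEASKMAKETLDDTERRNSTPSGAYPHTYLGVELLSVANDIMIMELNQICWVLRFLLFD
>nirK_ref09 synthetic seed-alignment member
GYATKGSCLDISQGGISKVEMDNPLGCESQLSADLIQIIIVQRMTRVLNKLANAAMNEQEASKGMEPDEDIGGKDYTEGAAHLMNGELEVSEADAGHILAECRAMLTLVVVAKWHEGESIDGATRPKGNQGHVVSAVKGDYQDFKNLENTGTFNMEPRYAGNAHKKSFYGWQLDADGIDDGGQKTNNQMDTDNYSHPDVSGLQSEPAQGPAYRLKPAKANLFSWSYAGQFVSVGAGTLFFPFIQCSFTINAVDFELRATDRGDEDIGEADATSMMPKRCMNCEANKNDKETMDDTERANSTPSGAYPHTELGVELLSVAGDIMIMELQQKCWVLEQLLFD
>nirK_ref10 synthetic seed-alignment member
GYATYGSPLDISAQGISKVYMKTPLGCESQLSADLIQIIIVMRMTRGLCKLANAAQNTNDADKGMEPHEMILHKRYTEGEAHLMVKELEVSEADAGLISQECRAMLTDVQVAKWHKGESIDGAMRPKGNQPSVVSAVKYDYQIFQNLECTGTLNMEPRLAMNAEKKSIQGSYLDAAHIDDHGQKTIAQMDTDNYKHPDVSGLQSEPLGGPAYKLKPLKACFFSASYAGQFHSVGFGTLFFPFIQCSETNNAVDFELRATDRGLEDIPEAFATSMMPKRCMLGEANKNAKETLDDTERRNSTFSGAYPHTYLGNELLSVANDIMIMELNQIDWVLEFLLFD
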