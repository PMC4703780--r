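>nirS_ref01 synthetic seed-alignment member
IQLALGVNARRGLVKPAIYLFGRTVGAEQVTNSAIMLNAPVRDDKSTLNEAMIQCKLSPIGPYGQSSVTTSVDLLKKIFHRDTLRCACQKSQVAVAKGKFASALDATNTARNTCYVLAKEIIRPFESFCDIGDAGYTMKNTMEKFKQPECLRLRMIQKVKPDAVVVSILVFTYDYVQSDEIKLCENEACVTNALIKYKVATAVQEEEDWFRLSDAIGARGRETSANDMTREAKKVNLAGTIVKDAGYELVHSLTGSTPALPLRSPFGKCEAKGFSTPRSVFDFHDRSGNIQYNLVAQGRCTNFSVIHQSLSRAGVEVLKNILSPTVVKECSAMQFKNSVLSVNEFAHTCPAQLCQGGDSPLMSTVPPVGAHSKLGRATAEDTFVMLMTDLLPEHVAGFIHVLYNLPVFYHGQGDTRSAEAHKACADYERRCILIQNFGSNHPSRIAALFRQTGSPLAKQWSAGVVLPLCGLDLLSHLVLKRNAILAIQTLLADGLFSPDAMPLDPDESTNNHMVHVRFQEVLFALTHALQYVASVDDPIQ
>nirS_ref02 synthetic seed-alignment member
IALALGMNARRGLVKPAIYIEGITVGAEQVTNSAIVLMAPVRQDKVTLNEAYIQCKLSPIGRGRQSSVTTWVMLLKIILHRDTLRCGCQQSQVAVAKEKFASELDAYNTARETSYKLAKEIIRPFESFCDIGDAGATMKNTEEKFKQAECLHLRMIQKGKPRAVVVSALVFTDDYVQTDEIHLCEKEACVTNATTKYKGPTAVQHEEDRFRESDAPGARGRETFANGMTREAKKFNLAGTIVMDATYELVESLTHITPALPLRSPFGKCEAKSLSGRRSVTDFATRSHNIQYNLVAQGRSNNASVKVQSGSRAGVEVLKNSLSPTVAKECMAHQFKNSVLSVGEFAHTCPAKLGQGRDSKMISTVLPGGAHSHLGRAGAWETFVMLGTVLLSEHEAGFIYVLYNLVVFYCGQGKLQSAEALKACADYEERCILLQNTGSNIVSEIAACFRKYGNPLAKQWSASVVLPLCGALLLSHLKVKRNAILAIQTLLASGLFSPDAWPFHVDEDTGMHEVHVRGQKVLGALTHALQQVASVDAAIQ
>nirS_ref03 synthetic seed-alignment member
IQLALGVTARRGLVKPAIYIFGITVGAEQVTRSAIELNAPVRNDKVV-NEAYIQCNLSPGARG-QSSSTTSEKLLKIKFHRDTCRCACQQSQVAVAKEKFASELDASNTFRETSYVIAKEIIRPFEMDCDIGDAGATMKNTEEKFKQAECKRLRMIQKVHPDAVVVSILTFFYDYVQSDIIKLCEKEACVVNAVIKYKGATAVQKEEDRFRESDAIGCRGREGFTNGMTGEACIVNLAGTIVMDAGYWKVESL-CITPALPLRSPFGKCETKGLS-RRSETDAADRSDNDQYN-VYQGRCQNASVIVQSLSRAGVEVLKNILSPTVVKECSAHQF-NVFLSVNEFAHTCPAKLGQGRDSKEISTVLPGGAHSKLGRATAESTFVMLGTVLRMEHQAGFI-VLSNLPVFYHYQGDTRS-EALKACADAERRLILLQNTGSNIPSEIAACFREYYSPLAKQWNAGVVLPLCGLLLLSTLVLKRNAILA-QTLLASGLFSPDAMPLQSDKSCT-HDVIVRGQ-VLGDLTHALQQNASVDDAIQ
>nirS_ref04 synthetic seed-alignment member
IQLALGVNARTCLVSPAIYIFGRTVGWEQVTESAIVLFAPMRDDKVT-NEAYISPKLSPIPRG-QSSVTTSVELLKIIFHRDTNRCACQQSQVAVAKEVPASELDARNTAREPSEVLAKEIIRPFESFCDIGDAGATMKNTEEKFKQAECTRLRMIDKVKLDAKVDDIIVDTYDYYQSDEIKLCEKEACVTNALIIYKRAMAHQKHEDRFRESFAIGARFREVFANGMTRAAKKVNLAGTIVKDAGYELVESL-CITPALPLRWPGDKCEAIGLS-RRSVTDFADRSGNIQYN-VAQGECNNASVIHQSLSLAGVEVLKNIYSGTVVKECSFHQF-SSVLSVNEFAHTCPAKLGQGRDSKMISTKLPGGAHSKLGRATAESTFVMLGVVLTSEHEAGFI-VLYNLKVFYHGYGDTRS-RAMKACADYERRCILLQNTGSNIPSEIAACFRRYGPPLAKQGSCGVVWFLCGLNLLSHLVLKRNYILA-QTLLASGLFSPDAMPLDPDESTG-HEVHVRGE-VLGGLTHALQYVASVDDAIQ
>nirS_ref05 synthetic seed-alignment member
IQLALGCNIARGLVKAAIYIFGGTVGAEQVTNSAIVLNAPVRDDKVTLNEAYIQCKLSPIGRHRLFSVTTSVLLLKIEFHRDTLRCAQQQSQVAVAKEKFAEELDAPNIALETSYYLAKEIIRPFESFCDVGDAGATMKNTEEKFKQAECLRLRLCQKVQPDAVVVSILVFTYDYVQSDEVKLCEKEPCVTNAMIKYKGATAMQKEEDRFRESDTIGYRRRETLASGMTREAKKVNLAGTIVKDAGNELVESLTCITPALILRSPFGKCEAKGLQGRRSVTDFADRTGNIQYNTVAQGRCENASVTHQSLSRAGVEKPKLILSHTFVKECSAHQFKNSVLFVNEFAHTCPAKLGQGRMIKMISTVLPGGAHSKLGRATAESTFVMLETVLLTMHEAGFIHVTYNLCVFYHGQGDTRSACVLKACADYEIVCILLQNTGSNIPSEIAACMRMYSSPLAKQWSNGVVLPYCGLLLLSHLVLKRKAILAIQTLLASGLFSPDKMPLMPKESTPNHEVHVRFQEVLGALTMALQQSASVDDAIQ
>nirS_ref06 synthetic seed-alignment member
IQLTLGVNARRGLVHWAIYIFGGTVGAEQVTNSAIVLNYQVRDDKVTLNEAYIQCKLSPIGRGRCSSVTTSVELLKIHGHRDTLCCACKQWQVAVAKEKFASELDASNTARETSYVLAKEIYWPHESGCDIGDAGATMTNTEEKFKQAECLRSRMIQKVKPDAVVVSILVFTQDYVQSDEIKLCEKEKCVWNALIKAKGQTAVQLEEDMFRESVNIGARGRETFANGMTREAKKVNLAGTIVKDAGYELVCSLTCITPALPLRSPFGKCEAKGLSGRRSVTDFNDRANNIQYNLVAQGRCSNARVIAPSLCRNHVEVLKNILHPTVVKECSAHYFKNSVLMVQEFTHTCPAKLGQGRDSKMISTVLPGGAHSKLGRATAESTFVMLGTALWSEHEAGFIHVLYNLPVFYHGQGDTRGACALFAAADGERRCILLQNTGSNIPSEIAACFRQYASPLAKMWSAGVVLRLCGLMLLSHLVLKRNIILAIQPLLASEAFEPDAMPLDPYESTGNHEVHPYGQEVLGSGTHALCQVASVDDIIQ
>nirS_ref07 synthetic seed-alignment member
IQLALGVNARRGLVKPAIYIFGGTVGAEQVTASAQVLNAPVRDDKVT-NEGYIQCKDSPIFRG-QSSVTTSVELLEIIFIDDTLPCACQQSQVAVAKEKFASELIASNTALETSYVLAKTISSPFESPCDIGDRGATMGNTEEKFKQAECLRLRMIGKHKPDAVCVSILVFYYDYKQSWEIKLCEKEACVTNALIKYKGATAVQKEEDRFLESDAIGARGRETFANGMWRWAKKVNLANTIVKDAGYELVESL-CITPALPHRSPFGKCEAKGLN-RRCVTDFADRGGNIQYN-VIQGWCKNAEVIHQSLSRKGVEVLKNILSPTVVVECSATQF-NSGLSSMESAHTCPAKLGQGRDSMMISTVLPGGAHSKLGRATAESTFVWLVTVLLSEHEAGDI-VLYNLPVFYHKQGDTRS-ESLKACADYLRRCILLQITGSNIPSECAACFRQYGSPLAKAWSDGVVLPLCRLLLLSHCVLKRNAYLA-QTLLVSGLFSPFAMPPDPDESTW-HEVHVRGQ-VLGASTKALQQRESVDDAIQ
>nirS_ref08 synthetic seed-alignment member
IQLGLGVNWCRGLVKPAIYIFLGTVGAEQVYNSDIVLNAPVQDDKGTLNEAYIQCKGSSIGRGRQISVTTSVELLKIIFHRDTLICACQQSVVAVAKEKIASELDASNFARNFVYVLAKEIIRPFASFCDIGDAQATMKNREEGFKQAECLPLRMIQKVKPLAVHVSIKVFTYDYVQSHEIKLCEKEACVTNALIKYKGATAVQKEEDRFRESDAIGARGRETFANGMTREAWKVNLAGTTVKDAGYEMVARLTCITRALPSRSPFGKFEAKGLVGRRSVTDMADRSGRIQYNLWAQGRCNNASVIDQSLSRAGVEWLKNILSPTPVKGESAHRFKNRVLSVNEFDHTCPAKLGQGRDSKMFSTVLPGGAHSKLGRATAESTFVHLGFVRLSEHEAGFIHPLYNLPWFYHGQGDTRSAEALKACADYERRCILLQNTGSNIPSEIAACFRQYGSPLAKDWSGGVVLPLGGTLLLSHLVLKRNAILAIQTTLASGLSSYDAMPLDPDESRGNDEVHVRGQEVLVALTHRLQQVASDDDAIQ
>nirS_ref09 synthetic seed-alignment member
IQLALGVNARRGLVKPAIYIFGGTVGAEQVTNSAIVLNAPVRDDKVTLNEYYIQCKLSPIGRGRQSSVTTSVELLKIHFHRDALRCACQQCQVAVMQSKFASETDASNSARETSYVLAKEIIREFESFYDIGDAGATMKNTEEKFKQAECLRLRMRQKVKPDAQVVSILVFTYDYVQSDIIKLQEKEACVTNALIKYKGATAVQKEEDRFRESDAIGARGRETFANGMTREAKKPNLAVTIVKDYHYNTAESHTCITPALPLSSPFGKCECDGLSGRRSVTDFEDRSGNIQYNLVAQKRCNNASVRHQSASRACVEVLKNILSPTMGKECIAHQFKESVLSVNEFAHTCPAKPGQGRDSKPISTVLPGGAHSKLGRATAESKFVSLGTVYLTEHPAGTIHVLYNLPVFMHGQGDTRSWAALKAYALYERRDILLQNTLSNTPSEIQACFRQYGSPLAEQWEAGDVLPLCSLHLLSHLVLKRNAILAIQVLKASGLFSFDAMPLDPDESTGNHEVHVRGQETLGALTRPIQQVDSVDDAIQ
>nirS_ref10 synthetic seed-alignment member
IQLALGVNYRRGLVKPFWHIMGWTVGAETVTNSAIWLNAPVRDDKVTMNEAYIECKLSTIGRGRQSSVTTSVELLKIIFHGDTLRCACLQKRVAQAKEKFASELDASNFARETSYVLAKEIIRPFPSFCKIGDAGATMKLTEEKFKQAECASLRMIQKVKPDARTVSIAVFTYDYVQSSEIKLCEKEACVTNALLKYKWATADTKEEDRRRESDAIGARGRETFANVMTREAKKVNLAGTIVKDRGYELVESLTCITPVLPLRSPLDKCEAKGLSGRRSVTDFADRSDNIQYNLVAQGRCNNASVIHQVLSRAGVEVLKNILSPTIVKECSAHQFKNSVLSVNEFYHTCGAKLGQGRDTKMISTVLPGGAHSKLGRATAEMTFVMTGTVLLNGGEAGFIHPLYNLPVFYHGQGDTRSAVELKACADYERRCELLQNTEANIPSFIAACFAQYGSPLAFQWSAGVVLPLKGLLLLSHLVLKRNAILASQTLLASGLFSPDAMPSDPDESTGYHEVHVRGQEGLGHLIHALQQAASVDYAIQ
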