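>nosZ_ref01 synthetic seed-alignment member
EKLWTPHKASLPRAVLMDGAVVGEEAIYSNLYYMKGLKGGESAKIFNKAAGSTLERQLLSRMSAHGADLEGRLLAYSANNSSNQDTAKEPSQKNSTASYLSLQTDDLPLATQRTYKFMGCEDTQEYSMSGYTFIIQENIFFFPFDEVGIETSAQKFHADYYTKEAKLYAVWTGKPIFTDAAEQFLDCADGKPDDYEYKCGTVLAWIHCPAELLITSFSTFFTSHFTGILLTSINFMKPDVIGLFLKGLVGEGYEESVSFQESTDADTVWWTTCQGRMNDPKYVSIEIPNRFMAIAKIKSGICKHDGIIDRPEVMDNFLRNIGKSVSFYLWGTHQFENFLVPILRPPTEMGIVMAENRRVALAPPQVTLASVGPARAKRSNSSPFCPVDTMFIEELRQRAVPVAVHLGIATTYVRIERALHPIKKLRRSYYQLLTSYIKYPSITGFEAVTIFKWTAGPAVGLDQNKADRDLTKARLYISGGWLGRGTLESEMVGVKCRVDCSHDDDPRQSAQKSTRDGRACMLFSDETQPPSKQQDQYGEEADRGTQDKQFYEAIYYRKSGHSAPLNFNFNVHKESIVAFT
>nosZ_ref02 synthetic seed-alignment member
EKLWTPHHASLPRAVLMFGAVVHYCALWNKLYGMKNLKGGESLKIFNKAPGATLERQLLVRMSAHGADKEGRLLAYSANNSSNGNTAYEPSQKNSTASYTSDQTDDLPLKTQRSAKFMGESCTQERSESGYMSIIQENITFAPFRRVGIETSAQKFHAEFKTKFAKLNVVHTGFVIFTDAAEEIKDCADDEPDDYEYKNMTVLAWIHCPAELLITYFSAMFISFFTGILLTSINFMKPDVIGLYLKGLVGVGYEESISFAEDTDLDAVWPTTVQGRMNDPKYVSIEIPNLFMNDEKIKSGCGKHDGIIDRPEGMDNFIRNIGKSVSFYLWGTHQFEPFLIPIRRPPTEMGGDMAETRRVELRPRDVTLAHVGPAWAVRSNSLDFCPVDTMDIFELRQMAVEVAVHLGIATTYVRIENALHPIKKLRRSYYQWLTSYIDYPSIAGFEAVTIFKWTAGPAVGLQKNKADRQLTKARLYISIGWFGRGALCSEMDGVHCRVDCSHDDPPHQQAQASTVDGFACMLFSSETQRPSRQQTEYGGEWDRGTNDKSKYEAIYYRLSGESAPANRNFNVHKESIEGFH
>nosZ_ref03 synthetic seed-alignment member
PKLVSPVSCSLPRAVLMDGAVVKPFQWYNKLYGMKGLKGGESLKIFNKAPGSTLERQLLSIMSAHGADKEGRLYAYSANASSNGDSAYEISTKNSTASYVDLQTDDLPLRTQRSAKFMGEEDTQERSESGYDDIIQWNITFKPFREVGIETSAQPSHADYKRKEAKCYVVHTLFVIFTDAAEEFLRCADGEPDDYKYMNGTVLAWISCPAELLITYFSKMFCSHFGCILCWSIAFMKPDVIGLFLKGLVGNGYEESISPQEDTDLDAVWPTTVQGTMNDPKYVSIEIPNRFMAWTKIKSNCGKHDQIILRPEGLDNFLRNIGKSVSFYLWYKWQFEPILVPILRPGTHMGGDMAENRSVDLSPPQVTLASVGPAAAKRSNSFEFCPVDTMDIEELRQRAVEVPVHLTIATTYVRIENALHPIHKLRRSYYQLLTSYIGYPSIAGFEAVTPFKWTAGPAVGLQQNAADRLLTKARLYISIGWLGRGTLESEMFGVKCRVDCSCDDQPRQQAQKSTVDGFACMHFSSECQPLSKQQDQYGDEWDRGTNDKSFYEAIYYRLRGESAPLNRNFNVHKESIVAFH
>nosZ_ref04 synthetic seed-alignment member
EKL-TTYMASLPRAVLMDGAVVKYEAWYNKLYGMKGLKGGESLKIFNKAPGSTLERQLPSRMS-HGADKE-RLLAYSANNFSNGDTAYEDSQKNSTA-YLSLQTDDLPLATQRFAKFMGSEDTQERSESLYTNIWQENITFAPFREVGIWTMAQKFHADPKTKENALYVVHTGFVIFTDHAEEFLDCADGEPDDYEYKNSTVLAWIHKPAELLITFFSVMFPSHFIGILLTQINFMKKDVIGL-LKGLVEVGYFESIVFQ-DTDLGAVWPATVQGS--DPKYVSIEIPNRCMAIAGIKNGCGKHDGIIDRPEGMDNFLRNEGKCESFYQWMAH-TEP-LVPQLDPPTEQGGDMRENRRVDLRPPCVFLANVG-AAEKRSNSQPFCWVDTMDIEELRYRAVEVAVHLTIATTYVPIENALHPIKKWHRSYYQLLTSHIKYPSIAGFFAVTIFTWTAGPAVGLQQNKADRDSTKARLYESIGWLGTGTLCSEMVGVKCRVDCSHDDCPRQQAQKSRVDM-ACMLFSSETQPPSKNQDQYGEEWDRGTNKECFYEAIYYRLSGESAPLNINFNVHKGSIKAFH
>nosZ_ref05 synthetic seed-alignment member
EKLITPYSAQLPRAVLMDGAVVKYEAWYNKLYGMKGLKGGESLKIFNKAPGSTKERKILSRMSAHGADKEGRALAYSLNNSSNGDGAYEPSQVNSTASYLSLVTDDLPLAFQRSAKFMAEEDTQERSESGYPNIIGDNITFAPIHEWGIETSAQKFHADYKTKEAKLYVVHTGFVIFTLAAEEFLFCADGEEDDYEYKNGTVLAWIHTPAELLITYFSMMFISHFTWILLKSINFMKPDVIGILLKGLDGVGYYESISFSEDTDLLAVKPTTVQGRMNDPKYVSIEIPNFFMVPAKIKSGCGKHCGIIDRPEWMDNFLRIIGKSVSFYDWGTHQFEPLTVPPLRPTTEIGGDMAENRRVDLRPPQVTLASVGPAAAKRSNSFPFCPVDTMDTEELRQRAVSVAAHLSIAFDYVRIENNLHQIKKLRRSYYQCLTSYIKYPSIAGFEAVTINKWDAGPAVGLQQGKADCDLHKARLIISIMWLGRGTLMSEMVGVKCRVDCSHDDDPWQQIWKSTVDGFACMLFSCETQPPSKQQDQYIEEWDRGTRDKSFYEAIYYRLMGESAPRNQNFNVHKESAVAFH
>nosZ_ref06 synthetic seed-alignment member
EKL-TPYSASLPRAVLMDGAVFKYEAWYFKLYGMKGLKGGEWLKIFNKAPGSTKERQLLSRMS-HGADKE-RLLAYSNNNSSNGDTAYQPIQKNSTV-YLSLQTYDLQLATQRSAKFMGEEVTQERSASGYREIIQENITFAPFREVRQETSAQKFHADYKTKEAKLYVVHTGFVIFRVAAEEFLDCFDSEPDDYEYKNGTVLAWIHEGTEQLITYFSKMFMSHFTGILLTSINFMKYDHIGL-LKGNVGGGAEESTYFQ-DTDLDQVWPTTVQGR--DPKYVSIEIPNRFEAIAKIKSGHGKHDGIIARPEGMDNFLQNIGKSVSFYPWGTH-FEP-LCPILLPPTEMGGAMAENRRADLRPPQVTIASVG-AAAKRSNSFPFCPVDTMDIEEPRQRAVEVAVHLIIATTYVRIENALHPIKPERRSDNQLLTSYIRPPSIPGFEAVTIVKWLAGPAVGLQQNKADRDRTKAELYISIGWLGRGTLCSYMVGVHYRVDCPHDDDPRQQLQKSTVFG-ACMLFSSETQPPSKQQDQYGNEWDRGTNDKAFYEAIYYRLSWESAPLNRNRYVHKESIVARH
>nosZ_ref07 synthetic seed-alignment member
EKLEKPYSASLPRAMLMDGAVVKYEAWYNKMYGMKGLKGCESLNIFNVPPGSTLERQLLSTMSAHGADKEGRLLAYSSNNSSNGDTAYEPSQKNSTASYLALQTDDLHLAWQRSPKFEGEEDTQERSRSGYTNIIQENITFAPFREVGIETSAQKFHADYKTKEQKLYVVHTGSVIFTDAADDFLDCADGEMIDYLYNNGTVLACIHCPAELLITYFSKMFISHGTGILLKRINFMKPDVIDLFLKGLVGVGLEESISFQEDTDVDAVWPTTVQGRMNDPKYVSIRIPNRFMAIAKIKSGCGKHDPIIDRPEGMDNGGRNIGKSVQCYMWGTHQFEPILVPIIRPPTEMGGDMRENRPVDLRHPQCTLFSVGPAAAKRGNSFPFCPVDTKDMEELRQRAVEVHVHLGIATTYVRIENMLHPIKKLRRSTYQLLTSYIKYPSIAGFEYVWNFDWTAGPAVGNQQNWDDRDLTKARLYISIGWLGRGVLCSEMVGVKCLVDCSHDDDKRQQAQKSTVIGFAEMLFSSETVPPSKQQDQYGEEWDRGTNDKSPYELCYYPLSGEYAPLNRNFDVHKESIVAFH
>nosZ_ref08 synthetic seed-alignment member
WKLITPYTASLPRAVLMDMAVVKYEAWYNKLYGIKGLKGNESLKIFNKAPGSTLERNLLSRMSAHGAKYIGRLLAKSANMSSNGDTAKEFSLKNSCASELSLQTDDLPLATQRSAEFMHEEDRQHRSISGYWNIIQENITDAPFAIVGIETSAQKGHADYKTKEAKLKVVHTVFVIFTDAAYEFLDCADGEPDDDEYKPGHVQAWIWCPAELLITYFSKMFISHFFGILLTSGNFMKPCVIGLFLKGLVGVGYEESIWFQEDTDLDAVWPTTVQGGMNDPKYVSIEIPNRFMAIALIKSGCGKHDGKIDRCCGQDNPLRNIGKSVSFVLWGTHQFEPFLINILRPITEMGGFMAENRRVDLRYPQVTLMSVGPAAAKRSNSFPFCPVDTQDIEEHRQRHDEVAVHLGIATTYVRIENALHPIKKFRRSYMQLLTNYIKYPKIAGFEAVTIFKWTAGPAVGEQQRKIDRDLTKARLYISIGWLGRGTLYSEMEGVKCRVDCSHDDDPRQQAQKSTVDGFACMLFSSETQPPSKQQDQYGEEWDRKTNDKEFYEAISYSLSGESAFLNRNFNVHKESIVAFH
>nosZ_ref09 synthetic seed-alignment member
EKLHTPYSASLERAVLMDGAVYKYEAWYMKLYRMLGLKGFESLIIFNKAPGSALEQQLLSRMSAHGADKFWMLQAYSANNSSNGDTAYAPMCKEYTASYLLKQTDDLPLATQRSAKFMREEDTQERSESGYTNIIQENITFAPFWPVGKETSAQKFHADYPTKEEKLYVVHTGFVIFWDGAEECLDCADGEPDDYTYKNGTVLAWIHSPAELLITYFSNMFISHFTGILLTSINHDKPDVIGLYLKGLKGVGYEEYISFQEDTDLDAVWPETVQGRMNHPKYVSINIPNRFMAIAKIKSGCGKHDGIIDLPPGMDNFLRNIGKSVSFYLWGTHYFEPFLVPILRPPTEMGGDMAEERAVVQRFPNVHLVSVGPAAAKRSNSFPFCPVDTMDIEELRQRAVEVAVHLGIATSYVRIQWALKMIKKLRRSYYQLLTSYIKYPSIAGFEEVTIDKWTAGPAVGLQQNKADRDLTKARTYISIGWLGRGTLCSEMVGVKCIVDCSEDDDPRQQAQKSTVDGFALMLFSSPTQTPSKQQDQYGEEWDRGTNTKSFYEAIYYRLSGESAPLRRNFRVHRMSIVAFH
>nosZ_ref10 synthetic seed-alignment member
EKL-TPYSASLPRAVLMDGAVVKYEAWYNKLYGMKGLKRGESLKIYNKAPGSTLERQLLSRMS-HGADRE-RLIAYSANNSSNGDKAYRPSWGNSTA-DLSLQTDDLPLATSRSAKFMGEQDTQERSESGYTVIIQRNITFAPFKLPGIETSAQKFHADYKTKEHKLYVVHTHFVIFCDAAEHFLDCADGEPDDYEYKNGTVLAWFMCPAELLITYFSKMFISHFTGIQSDSINWMKPDVIGL-LKGLVWVGYEESISFQ-DTILDAVWPTYWQGR--DPKYVSQEIPVRFMAIAKIKSGCGKHDGIPDRPEGIDNFLRNDGMSVSFYLWGTH-FEG-LVPICRPPTEMGGDMAEPRQIDLQKPQVTWASVG-AAAKRSNSFPFCPVDTMDIEQLRQRAVEVAVHLGIAFTYRRIENAHHPPKKLRRSYYQLLTSYIKYDQIAGFLAVTIKKWTAGPAVGLPQNKADRPLTKARLYISIGWLGRMTLCSEMVGVKCRVDCSHDDDPRQQCQKSTVDG-ACALFSLETQPPSPQQDQYGEEHDRGTNEKSFYEAIYYRTPGESAPLNRNFNVHKEVIVAFH
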