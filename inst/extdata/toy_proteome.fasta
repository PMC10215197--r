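>MT001 toy protein 1
DARVTYRADRLIYVWSGIPKWKCYMIHKAHAYFAMQQHGKSPCELFASTWCEWPNKRNVC
PKILKTCIFGTNRREFKCDDSQLSMMNNIDASSLKMWSVLTKIMWIHTMPIDANSYMFDW
TWRSMCRV
>MT002 toy protein 2
GSWCDECPQGIPGCKRPDTMCLCVQRCSHHVHRWMGGDYQESSDGRECGRRKKLRSSYLW
HCHAVNETFQKVWTITYVCTAQWQCKNQCEKAGRYTHKTKCTVCCLDQCELKGRTTMPRQ
DLRYCDYRGVRYQQHVIVKCAQCVKQKYSQIQRSMRKVVKQYDICQQRALRCDEFYAHIR
>MT003 toy protein 3
ETDIWSSDKCHFVLQGEHRGIKKAIGDHTKCSVPDLVTFEAFTMDIERQSRPACRKWTVI
EMWRACRYLFNPLAYTRKLFHYRAERIRTNPRCNGHKRVAGTKVQPLLTVRDKHNRVFDI
WEVRGFKHIPFHQNFYWIRWKRFQ
>MT004 toy protein 4
CIYQKDDLVMYCGNTWRYVYNRKAVWHVCSECKRCLGRYTRYNCGNELQCEQTGDWRFPK
DVEWNGFHRKLLNPALCTSFNQQYCPRRRDEYGGCKKEQSNLSF
>MT005 toy protein 5
CAKCFKKMTNDFFCVAAVPQWHAGVTQKVLEGELVGCHLVLPQWDRCVQVMNSCPEHPVQ
NNNTPRLWPQRTWLPLIADCAYPLVCRVQGYQWNSTHWEVGRIRRNEEILYSAQWRRSTM
RYWKPLDDVSLCPSPCEQTYYISGSIEKFCMRI
>MT006 toy protein 6
QWIHHMHAADRVQFFWDTLDYHKGDINRICRNTRADAPRKPPDHHTHRICSKDYSDMFIK
PREFIKYIFKMEHRWRDYCLLCLNELCDLMSMDRKTNFIKKANKNKNHKIMMEFDKGGKT
TREQGCLSEHFKTDHDAPECQWKCVQGYKWHFRVDTDSFGDCCRWGEVMIIDIKPPRKH
>MT007 toy protein 7
KTDQNTRIQDDSSATNRGAARMWRICVVDYDGRKQNGLLKQSIKPTKQHQSIMMGFPHFK
WRYKCGCHVMTKCEIPRHKVGVNYREYSRWWRRTKLK
>MT008 toy protein 8
WKWTLKTPNGHTCCCWREGEYKQQRIVKADACKRITDFVRDQIMSCMWAKWCRPEWFLKE
KYRKIPYNIMTKVDNPDKRRHAISPKDLPKDKGLELLRDTKFMKHFGIGYMIDSKRWGKD
PYLQWGLG
>MT009 toy protein 9
KVKSPKVMEKILNDHPCNKQHRWKAGLDVLWCLHQVKNRIFHKPWYRKHALALRTNSGVV
HYTPQRDFKRWVHHFCWDGLNFDAKIGTEHKWKFMQAWMRYTGKNSWLFVTRWHGDEWFG
CSSSQK
>MT010 toy protein 10
FKFEIDPPPNHTYMDQNPNHPFCSQIGIEEKFSFKLREKPGRMIPIGAVRRYPYYVKPEQ
IQRTSLEVYDLSSWDHMNWDMFKNLLSEPTHWRQSTCPRESKR
>CY001 toy protein 11
HMCLWRVYHEKYRQPEHVNIKIACYRCSECTRVQYCLKLIKTVMKFQCCIFCHEQRERVS
KIWIVAGVAECGYQDDGIFEARQMNDMIMMYFYDTSIRDNKNNTFLRFMNNIQGNVWNVW
QLGCAALRTKAKTSCEVIFMSQRKAKDIPT
>CY002 toy protein 12
EKHMKFRYRTNTDSHLFVETSGGQYQPCACCMSDSCEHWCFWFIYTVFSRHVTHASCRSR
AGHEANRTFIRAKMCTRWQVCLLRSKCRLTKCTSFSRMPHARTIIQASGYFPDRDDRWSM
EKQCNVKGGRCAYKSHKICNDIEGKCAKPTILALASPLKGQKMRCFCINWKCDSWNRRH
>CY003 toy protein 13
IRLSRINYRWWKSECRPVHMRRFGIGGYHRYEEWMFFNMVTGLRVMDKWREWDRTKECTK
HTTNCSCMDCWQCLCNACADNIRYATMPTCLLDVHRDQHIPMCQTSYSHKYRAKWIHATF
QRAFKILTTTMKKYMWTQYKPKYWCWVNTPMFNDDPEAKMFGSWWVCA
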