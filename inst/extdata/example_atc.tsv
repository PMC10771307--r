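generic_name	atc_code
furosemide	C03CA01
quetiapine	N05AH04
citalopram	N06AB04
ondansetron	A04AA01
metoprolol	C07AB02
omeprazole	A02BC01
acetaminophen	N02BE01
acetylsalicylic acid	B01AC06
acetylsalicylic acid	N02BA01
amiodarone	C01BD01
levothyroxine sodium	H03AA01
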