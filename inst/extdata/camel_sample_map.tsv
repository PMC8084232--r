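# sample -> population map; population sizes follow the seven-site design (synthetic sample ids)
sample_id	population_code
NJ01	NJ
NJ02	NJ
NJ03	NJ
NJ04	NJ
NJ05	NJ
NJ06	NJ
NJ07	NJ
BJ01	BJ
BJ02	BJ
BJ03	BJ
BJ04	BJ
BJ05	BJ
BJ06	BJ
BJ07	BJ
DJ01	DJ
DJ02	DJ
DJ03	DJ
DJ04	DJ
DJ05	DJ
DJ06	DJ
DJ07	DJ
HX01	HX
HX02	HX
HX03	HX
HX04	HX
HX05	HX
QH01	QH
QH02	QH
QH03	QH
QH04	QH
QH05	QH
QH06	QH
QH07	QH
ALS01	ALS
ALS02	ALS
ALS03	ALS
ALS04	ALS
ALS05	ALS
ALS06	ALS
ALS07	ALS
SNT01	SNT
SNT02	SNT
SNT03	SNT
SNT04	SNT
SNT05	SNT
SNT06	SNT
SNT07	SNT
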