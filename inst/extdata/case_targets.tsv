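herb	gene
mulberry leaf	CSF2
mulberry leaf	TNF
mulberry leaf	IL2
mulberry leaf	IL4
mulberry leaf	IL6
mulberry leaf	IL10
mulberry leaf	T007
mulberry leaf	T008
mulberry leaf	T009
mulberry leaf	T010
mulberry leaf	T011
mulberry leaf	T012
mulberry leaf	T013
mulberry leaf	T014
mulberry leaf	T015
mulberry leaf	T016
mulberry leaf	T017
mulberry leaf	T018
mulberry leaf	T019
mulberry leaf	T020
mulberry leaf	T021
mulberry leaf	T022
mulberry leaf	T023
mulberry leaf	T024
mulberry leaf	T025
mulberry leaf	T026
mulberry leaf	T027
mulberry leaf	T028
mulberry leaf	T029
mulberry leaf	T030
bitter apricot kernel	T031
bitter apricot kernel	T032
bitter apricot kernel	T033
bitter apricot kernel	T034
bitter apricot kernel	T035
bitter apricot kernel	T036
bitter apricot kernel	T037
bitter apricot kernel	T038
bitter apricot kernel	T039
bitter apricot kernel	T040
bitter apricot kernel	T041
bitter apricot kernel	T042
bitter apricot kernel	T043
bitter apricot kernel	T044
bitter apricot kernel	T045
bitter apricot kernel	T046
bitter apricot kernel	T047
bitter apricot kernel	T048
bitter apricot kernel	T049
bitter apricot kernel	T050
bitter apricot kernel	T051
bitter apricot kernel	T052
bitter apricot kernel	T053
bitter apricot kernel	T054
bitter apricot kernel	T055
liquorice	T056
liquorice	T057
liquorice	T058
liquorice	T059
liquorice	T060
liquorice	T061
liquorice	T062
liquorice	T063
liquorice	T064
liquorice	T065
liquorice	T066
liquorice	T067
liquorice	T068
liquorice	T069
liquorice	T070
liquorice	T071
liquorice	T072
liquorice	T073
liquorice	T074
liquorice	T075
liquorice	T076
liquorice	T077
liquorice	T078
forsythia suspensa	S001
forsythia suspensa	S002
forsythia suspensa	S003
forsythia suspensa	S004
forsythia suspensa	S005
chrysanthemum	S006
chrysanthemum	S007
chrysanthemum	S008
reed rhizome	S009
reed rhizome	S010
common hogfennel root	S011
common hogfennel root	S012
platycodon root	S013
platycodon root	S014
platycodon root	S015
fermented soybean	K001
fermented soybean	K002
fermented soybean	K003
thunberg fritillary bulb	K004
thunberg fritillary bulb	K005
thunberg fritillary bulb	K006
thunberg fritillary bulb	K007
thunberg fritillary bulb	K008
radix adenophorae	K009
radix adenophorae	K010
white mulberry root-bark	K011
white mulberry root-bark	K012
cape jasmine fruit	K013
cape jasmine fruit	K014
cape jasmine fruit	K015
root of doubleteeth pubescent angelica	TNF
root of doubleteeth pubescent angelica	IL6
root of doubleteeth pubescent angelica	D001
root of doubleteeth pubescent angelica	D002
mistletoe	D003
mistletoe	D004
radix gentianae macrophyllae	IL8
radix gentianae macrophyllae	D005
radix gentianae macrophyllae	D006
radix saposhnikoviae	TNF
radix saposhnikoviae	IL8
radix saposhnikoviae	D007
radix saposhnikoviae	D008
manchurian wildginger	D009
manchurian wildginger	D010
chinese angelica	IL6
chinese angelica	IL10
chinese angelica	D011
chinese angelica	D012
szechwan lovage rhizome	D013
szechwan lovage rhizome	D014
chinese herbaceous peony	IL2
chinese herbaceous peony	D015
drying rehmannia root	D016
drying rehmannia root	D017
bark of eucommia	D018
radix achyranthis bidentatae	D019
ginseng root	CSF2
ginseng root	D020
tuckahoe	IL4
tuckahoe	D021
cassia bark	D022
cassia twig	D023
cassia twig	D024
notopterygium root	TNF
notopterygium root	IL6
notopterygium root	D025
notopterygium root	D026
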