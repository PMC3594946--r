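name	herbs	diseases	doids
abstract pair f1	herb 1|herb 2|herb 3|herb 4|herb 5		
abstract pair f2	herb 2|herb 4|herb 6|herb 7		
ssjy	mulberry leaf|chrysanthemum|forsythia suspensa|reed rhizome|common hogfennel root|bitter apricot kernel|platycodon root|liquorice	chronic bronchitis	DOID:6132
skt	mulberry leaf|fermented soybean|thunberg fritillary bulb|radix adenophorae|white mulberry root-bark|cape jasmine fruit|bitter apricot kernel|liquorice	chronic bronchitis	DOID:6132
sjzby	mulberry leaf|chrysanthemum|thunberg fritillary bulb|reed rhizome|common hogfennel root|bitter apricot kernel|platycodon root|liquorice	chronic bronchitis	DOID:6132
fdhjst	root of doubleteeth pubescent angelica|mistletoe|radix gentianae macrophyllae|radix saposhnikoviae|manchurian wildginger|chinese angelica|szechwan lovage rhizome|chinese herbaceous peony|drying rehmannia root|bark of eucommia|radix achyranthis bidentatae|ginseng root|tuckahoe|cassia bark|liquorice	rheumatoid arthritis	DOID:7148
fft	radix saposhnikoviae|chinese angelica|radix gentianae macrophyllae|cassia twig|bitter apricot kernel|notopterygium root|tuckahoe|liquorice	rheumatoid arthritis	DOID:7148
ffdht	radix saposhnikoviae|chinese angelica|radix gentianae macrophyllae|tuckahoe|root of doubleteeth pubescent angelica|liquorice	rheumatoid arthritis	DOID:7148
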