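name	natures	tastes	channels	functions	indications
mulberry leaf	slight cold	bitter|sweet	lung|liver	dispersing wind heat|clearing lung heat|improving vision	cough|headache|red eyes
chrysanthemum	slight cold	spicy|sweet|bitter	lung|liver	dispersing wind heat|improving vision|calming liver	headache|red eyes|dizziness
forsythia suspensa	slight cold	bitter	lung|heart	clearing heat|removing toxin|dispersing wind heat|relieving cough|reducing swelling	cough|fever|sore throat
reed rhizome	cold	sweet	lung|stomach	clearing heat|promoting fluid|relieving vomiting	thirst|vomiting|lung abscess
common hogfennel root	slight cold	bitter|spicy	lung	descending qi|expelling phlegm	wind heat cough|thick phlegm
bitter apricot kernel	slight warm	bitter	lung|large intestine	relieving cough|calming wheezing|moistening intestines	cough|asthma|constipation
platycodon root	ping	bitter|spicy	lung	opening lung qi|expelling phlegm|easing throat	cough with phlegm|sore throat
liquorice	ping	sweet	heart|lung|spleen|stomach	tonifying spleen|moistening lung|harmonizing herbs|removing toxin	cough|sore throat|spleen weakness
fermented soybean	ping	spicy|sweet	lung|stomach	relieving exterior|eliminating irritability	common cold|insomnia
thunberg fritillary bulb	slight cold	bitter|sweet	lung|heart	clearing heat|relieving cough|dissipating nodules|moistening lung	cough|fever|scrofula
radix adenophorae	slight cold	sweet	lung|stomach	nourishing yin|moistening lung|expelling phlegm	dry cough|thirst
white mulberry root-bark	cold	sweet	lung	purging lung heat|promoting urination	wheezing|edema
cape jasmine fruit	cold	bitter	heart|lung|three warmers	purging fire|eliminating irritability|cooling blood	fever|irritability|jaundice
root of doubleteeth pubescent angelica	warm	spicy|bitter	kidney|bladder	dispelling wind damp|relieving pain	rheumatic pain|headache
mistletoe	ping	bitter	liver|kidney	dispelling wind damp|strengthening tendons and bones|calming fetus	rheumatic pain|weak lower back
radix gentianae macrophyllae	ping	bitter|spicy	stomach|liver|gallbladder	dispelling wind damp|clearing deficiency heat	rheumatic pain|tidal fever
radix saposhnikoviae	slight warm	spicy|sweet	bladder|liver|spleen	relieving exterior|dispelling wind damp|stopping spasm	common cold|rheumatic pain|tetanus
manchurian wildginger	warm	spicy	lung|kidney|heart	warming lung|resolving fluid retention|dispersing cold	cold phlegm|toothache
chinese angelica	warm	sweet|spicy	liver|heart|spleen	harmonizing the blood|regulating menses|moistening intestines	irregular menses|blood deficiency|constipation
szechwan lovage rhizome	warm	spicy	liver|gallbladder|pericardium	activating blood|moving qi|dispelling wind|relieving pain	headache|irregular menses
chinese herbaceous peony	slight cold	bitter|sour	liver|spleen	nourishing blood|softening liver|relieving pain	abdominal pain|irregular menses
drying rehmannia root	cold	sweet|bitter	heart|liver|kidney	clearing heat|cooling blood|nourishing yin	fever|thirst|bleeding
bark of eucommia	warm	sweet	liver|kidney	tonifying liver and kidney|strengthening tendons and bones|calming fetus	weak lower back|dizziness
radix achyranthis bidentatae	ping	bitter|sour	liver|kidney	activating blood|strengthening tendons and bones|guiding downward	weak knees|amenorrhea
ginseng root	slight warm	sweet	spleen|lung|heart	tonifying qi|generating fluid|calming spirit	fatigue|thirst|palpitation
tuckahoe	ping	sweet|tasteless	heart|spleen|kidney	promoting urination|strengthening spleen|calming spirit	edema|insomnia|poor appetite
cassia bark	hot	spicy|sweet	kidney|spleen|heart	warming interior|strengthening yang|dispersing cold	cold limbs|weak yang
cassia twig	warm	spicy|sweet	heart|lung|bladder	warming channels|relieving exterior|assisting yang	common cold|cold limbs|palpitation
notopterygium root	warm	spicy|bitter	kidney|bladder	dispelling wind damp|relieving pain|dispersing cold	rheumatic pain|common cold
rhinoceros horn	cold	bitter|salty	heart|liver	clearing heat|cooling blood|removing toxin	high fever|convulsion|macula
buffalo horn	cold	bitter|salty	heart|liver	clearing heat|cooling blood|removing toxin	high fever|convulsion
walnut kernel	warm	sweet	kidney|lung	tonifying kidney|warming lung|moistening intestines	impotence|chronic cough|constipation
cordyceps sinensis	warm	sweet	kidney|lung	tonifying kidney|warming lung|stopping bleeding	impotence|chronic cough|weakness
herb 1	ping	sweet	spleen	function a	symptom a
herb 2	ping	sweet	spleen	function b	symptom b
herb 3	ping	sweet	spleen	function c	symptom c
herb 4	ping	sweet	spleen	function d	symptom d
herb 5	ping	sweet	spleen	function e	symptom e
herb 6	ping	sweet	spleen	function f	symptom f
herb 7	ping	sweet	spleen	function g	symptom g
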