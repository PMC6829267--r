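category	keyword
carbohydrate metabolism	raffinose
carbohydrate metabolism	glucosidase
carbohydrate metabolism	galactosidase
carbohydrate metabolism	galactinol
carbohydrate metabolism	sucrose
carbohydrate metabolism	starch
carbohydrate metabolism	invertase
carbohydrate metabolism	trehalose
lipid metabolism	lipase
lipid metabolism	phospholipase
lipid metabolism	wax
lipid metabolism	lipid
lipid metabolism	desaturase
lipid metabolism	aldehyde decarboxylase
cell wall modification	chitinase
cell wall modification	pectate
cell wall modification	pectin
cell wall modification	cellulose
cell wall modification	polygalacturonase
cell wall modification	xyloglucan
cell wall modification	expansin
cell wall modification	cell wall
circadian rhythm	circadian
circadian rhythm	clock
circadian rhythm	CCA1
circadian rhythm	LHY
calcium signaling	calcium
calcium signaling	calmodulin
calcium signaling	annexin
calcium signaling	Ca2+
calcium signaling	calcineurin
transcription factor	transcription factor
transcription factor	bHLH
transcription factor	WRKY
transcription factor	MYB
transcription factor	zinc finger
transcription factor	GRAS
transcription factor	Dof
transcription factor	ethylene-responsive factor
hormone signaling	auxin
hormone signaling	gibberellin
hormone signaling	abscisic
hormone signaling	ethylene
hormone signaling	jasmon
hormone signaling	GH3
hormone signaling	DELLA
hormone signaling	JAZ
hormone signaling	MYC2
hormone signaling	indole-3-acetic
kinase	kinase
chloroplast	chloroplast
chloroplast	photosystem
chloroplast	chlorophyll
chloroplast	thylakoid
transporter	transporter
transporter	ABC
transporter	channel
transporter	ATPase
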