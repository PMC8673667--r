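term	class	match	provenance
cell	cell	component	core
cellular	cell	component	core
viability	cell	component	curated; viability phrases treated as cell terms
lymphocyte	cell	component	curated
thymocyte	cell	component	curated
hepatocyte	cell	component	curated
neuron	cell	component	curated
neuronal	cell	component	curated
astrocyte	cell	component	standard-synonym
fibroblast	cell	component	standard-synonym
keratinocyte	cell	component	standard-synonym
macrophage	cell	component	standard-synonym
monocyte	cell	component	standard-synonym
erythrocyte	cell	component	standard-synonym
leukocyte	cell	component	standard-synonym
myocyte	cell	component	standard-synonym
cardiomyocyte	cell	component	standard-synonym
oocyte	cell	component	standard-synonym
osteoblast	cell	component	standard-synonym
osteoclast	cell	component	standard-synonym
splenocyte	cell	component	standard-synonym
proliferation	proliferation	component	core
proliferative	proliferation	component	core
proliferate	proliferation	component	curated
growth	proliferation	component	curated
mitosis	proliferation	component	curated
mitotic	proliferation	component	curated
division	proliferation	component	definition
expansion	proliferation	component	standard-synonym
regeneration	proliferation	component	standard-synonym
accumulation	proliferation	component	curated
loss	proliferation	component	curated; also outcome-level negation marker
death	death	component	core
apoptosis	death	component	core
apoptotic	death	component	curated
necrosis	death	component	core
necrotic	death	component	curated
arrest	death	component	curated; cell-cycle-arrest expressions are death-class
kill	death	component	curated
demise	death	component	standard-synonym
autophagy	death	component	standard-synonym
pyroptosis	death	component	standard-synonym
ferroptosis	death	component	standard-synonym
anoikis	death	component	ontology
apoptosis	death	standalone	core
necrosis	death	standalone	core
death	death	standalone	curated
apoptotic	death	standalone	curated
anoikis	death	standalone	ontology
pyroptosis	death	standalone	standard-synonym
ferroptosis	death	standalone	standard-synonym
angioproliferate	proliferation	standalone	curated
mitogen	proliferation	standalone	curated
mitotic index	proliferation	standalone	curated
proliferative index	proliferation	standalone	standard-synonym
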