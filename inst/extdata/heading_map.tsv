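heading	label
background	background
introduction	background
context	background
objective	objective
objectives	objective
aim	objective
aims	objective
purpose	objective
goal	objective
methods	methods
method	methods
materials and methods	methods
design	methods
study design	methods
setting	methods
participants	methods
results	results
result	results
findings	results
main results	results
main findings	results
observations	results
conclusion	conclusions
conclusions	conclusions
interpretation	conclusions
discussion	conclusions
significance	conclusions
unlabelled	unlabeled
unassigned	unlabeled
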