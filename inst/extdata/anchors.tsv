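# Anchor-term seed configuration: base verb and category.
# Categories: increase, decrease, general_change, causality.
# The three directionality categories ship with 58 + 86 + 71 = 215 bases;
# counts are configuration, not ground truth - edit freely.
base	category
increase	increase
induce	increase
enhance	increase
elevate	increase
stimulate	increase
promote	increase
upregulate	increase
up-regulate	increase
augment	increase
trigger	increase
accelerate	increase
amplify	increase
boost	increase
raise	increase
potentiate	increase
exacerbate	increase
aggravate	increase
intensify	increase
facilitate	increase
activate	increase
enlarge	increase
expand	increase
escalate	increase
heighten	increase
magnify	increase
maximize	increase
multiply	increase
prolong	increase
strengthen	increase
double	increase
triple	increase
grow	increase
rise	increase
gain	increase
accumulate	increase
advance	increase
build	increase
climb	increase
deepen	increase
broaden	increase
surge	increase
soar	increase
inflate	increase
fortify	increase
reinforce	increase
invigorate	increase
accentuate	increase
overexpress	increase
hyperactivate	increase
upsurge	increase
contribute	increase
foster	increase
fuel	increase
spur	increase
propagate	increase
exaggerate	increase
overproduce	increase
sensitize	increase
decrease	decrease
reduce	decrease
inhibit	decrease
suppress	decrease
attenuate	decrease
diminish	decrease
downregulate	decrease
down-regulate	decrease
prevent	decrease
block	decrease
abolish	decrease
abrogate	decrease
lower	decrease
decline	decrease
deplete	decrease
impair	decrease
lessen	decrease
weaken	decrease
ameliorate	decrease
alleviate	decrease
mitigate	decrease
minimize	decrease
curtail	decrease
dampen	decrease
decelerate	decrease
drop	decrease
fall	decrease
halve	decrease
hamper	decrease
hinder	decrease
impede	decrease
limit	decrease
counteract	decrease
antagonize	decrease
blunt	decrease
eliminate	decrease
eradicate	decrease
halt	decrease
quench	decrease
repress	decrease
restrain	decrease
retard	decrease
shorten	decrease
shrink	decrease
slow	decrease
subside	decrease
wane	decrease
deprive	decrease
degrade	decrease
deteriorate	decrease
downmodulate	decrease
neutralize	decrease
nullify	decrease
obstruct	decrease
oppose	decrease
preclude	decrease
restrict	decrease
reverse	decrease
stall	decrease
stifle	decrease
stop	decrease
subdue	decrease
terminate	decrease
thwart	decrease
undermine	decrease
lose	decrease
deactivate	decrease
inactivate	decrease
silence	decrease
disable	decrease
cease	decrease
avert	decrease
ablate	decrease
contract	decrease
compress	decrease
taper	decrease
dwindle	decrease
plummet	decrease
recede	decrease
regress	decrease
remit	decrease
shrivel	decrease
wither	decrease
extinguish	decrease
annul	decrease
forestall	decrease
change	general_change
alter	general_change
affect	general_change
modulate	general_change
modify	general_change
influence	general_change
effect	general_change
regulate	general_change
vary	general_change
shift	general_change
impact	general_change
convert	general_change
transform	general_change
adjust	general_change
perturb	general_change
disturb	general_change
disrupt	general_change
interfere	general_change
deregulate	general_change
dysregulate	general_change
fluctuate	general_change
oscillate	general_change
remodel	general_change
reorganize	general_change
restructure	general_change
switch	general_change
transition	general_change
redistribute	general_change
rearrange	general_change
reprogram	general_change
reshape	general_change
alternate	general_change
destabilize	general_change
stabilize	general_change
equilibrate	general_change
rebalance	general_change
recalibrate	general_change
displace	general_change
divert	general_change
mutate	general_change
reconfigure	general_change
transmute	general_change
waver	general_change
swing	general_change
turn	general_change
adapt	general_change
evolve	general_change
differ	general_change
deviate	general_change
diverge	general_change
drift	general_change
metamorphose	general_change
permute	general_change
skew	general_change
tilt	general_change
warp	general_change
bend	general_change
refashion	general_change
remold	general_change
morph	general_change
translocate	general_change
transpose	general_change
invert	general_change
exchange	general_change
interchange	general_change
substitute	general_change
supplant	general_change
transfigure	general_change
unsettle	general_change
upset	general_change
veer	general_change
cause	causality
kill	causality
arrest	causality
mediate	causality
drive	causality
elicit	causality
evoke	causality
generate	causality
produce	causality
provoke	causality
yield	causality
determine	causality
govern	causality
control	causality
underlie	causality
implicate	causality
confer	causality
render	causality
exert	causality
involve	causality
participate	causality
respond	causality
react	causality
predispose	causality
initiate	causality
originate	causality
instigate	causality
precipitate	causality
engender	causality
incite	causality
actuate	causality
catalyze	causality
effectuate	causality
occasion	causality
prompt	causality
motivate	causality
dictate	causality
steer	causality
orchestrate	causality
commit	causality
depend	causality
rely	causality
require	causality
necessitate	causality
entail	causality
impose	causality
force	causality
compel	causality
dispose	causality
enable	causality
permit	causality
allow	causality
predicate	causality
subject	causality
condition	causality
ordain	causality
underpin	causality
direct	causality
program	causality
shape	causality
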