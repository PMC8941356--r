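keyword,category
hallux,toes
great toe,toes
big toe,toes
little toe,toes
toe,toes
toes,toes
digit,toes
phalanx,toes
interdigital,toes
metatarsal,forefoot
metatarsal head,forefoot
ball of foot,forefoot
ball of the foot,forefoot
forefoot,forefoot
transmetatarsal,forefoot
heel,hindfoot
calcaneus,hindfoot
calcaneal,hindfoot
hindfoot,hindfoot
ankle,leg
malleolus,leg
malleolar,leg
shin,leg
calf,leg
pretibial,leg
tibial,leg
lower leg,leg
leg,leg
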