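gestation:
  terms:
  - gestation
  - gestational
  class: pregnancy-condition
  exclusivity_exempt: yes
parturition:
  terms:
  - parturition
  - parturient
  class: pregnancy-condition
  exclusivity_exempt: no
pregnancy:
  terms:
  - pregnancy
  - pregnancies
  - pregnant
  - gravid
  class: pregnancy-condition
  exclusivity_exempt: yes
preterm:
  terms:
  - preterm
  - premature
  - prematurity
  class: pregnancy-condition
  exclusivity_exempt: no
cervix:
  terms:
  - cervix
  - cervical
  class: female-anatomy
  exclusivity_exempt: no
endometrium:
  terms:
  - endometrium
  - endometrial
  class: female-anatomy
  exclusivity_exempt: no
myometrium:
  terms:
  - myometrium
  - myometrial
  class: female-anatomy
  exclusivity_exempt: no
uterus:
  terms:
  - uterus
  - uterine
  - utero
  class: female-anatomy
  exclusivity_exempt: no
fetus:
  terms:
  - fetus
  - foetus
  - fetal
  - foetal
  - embryo
  - embryonic
  class: fetal-anatomy
  exclusivity_exempt: no
chorion:
  terms:
  - chorion
  - chorionic
  class: fetal-anatomy
  exclusivity_exempt: no
amnion:
  terms:
  - amnion
  - amniotic
  class: fetal-anatomy
  exclusivity_exempt: no
placenta:
  terms:
  - placenta
  - placental
  class: fetal-anatomy
  exclusivity_exempt: no
ageing:
  terms:
  - ageing
  - aging
  class: control-condition
  exclusivity_exempt: yes
obesity:
  terms:
  - obesity
  - obese
  class: control-condition
  exclusivity_exempt: yes
asthma:
  terms:
  - asthma
  - asthmatic
  class: control-condition
  exclusivity_exempt: yes
migraine:
  terms:
  - migraine
  - migraines
  class: control-condition
  exclusivity_exempt: yes
insomnia:
  terms: insomnia
  class: control-condition
  exclusivity_exempt: yes
hypertension:
  terms:
  - hypertension
  - hypertensive
  class: control-condition
  exclusivity_exempt: yes
diabetes:
  terms:
  - diabetes
  - diabetic
  class: control-condition
  exclusivity_exempt: yes
epilepsy:
  terms:
  - epilepsy
  - epileptic
  class: control-condition
  exclusivity_exempt: yes
kidney:
  terms:
  - kidney
  - renal
  class: control-anatomy
  exclusivity_exempt: yes
liver:
  terms:
  - liver
  - hepatic
  class: control-anatomy
  exclusivity_exempt: yes
retina:
  terms:
  - retina
  - retinal
  class: control-anatomy
  exclusivity_exempt: yes
cochlea:
  terms:
  - cochlea
  - cochlear
  class: control-anatomy
  exclusivity_exempt: yes
pancreas:
  terms:
  - pancreas
  - pancreatic
  class: control-anatomy
  exclusivity_exempt: yes
thyroid:
  terms: thyroid
  class: control-anatomy
  exclusivity_exempt: yes
tendon:
  terms:
  - tendon
  - tendinous
  class: control-anatomy
  exclusivity_exempt: yes
skin:
  terms:
  - skin
  - cutaneous
  class: control-anatomy
  exclusivity_exempt: yes
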