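# Tokens removed from food descriptions when forming the pairing key.
# One entry per line; matched case-insensitively against whole comma-separated
# description tokens. Edit to tune pairing.
raw
cooked
boiled
steamed
roasted
grilled
broiled
boiling
steaming
roasting
grilling
broiling
drained
without salt
with salt
unprepared
prepared
fresh
frozen
all grades
choice
select
trimmed to 0" fat
trimmed to 1/8" fat
trimmed to 1/4" fat
separable lean only
separable lean and fat
meat only
meat and skin
skin removed
bone removed
bone-in
boneless
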