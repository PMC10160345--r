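# Markers indicating a multi-ingredient or recipe food (excluded from pairing).
# Matched case-insensitively as substrings of the description.
recipe
made with
canned
includes
stuffed
luncheon
salad
soup
sauce
gravy
casserole
breaded
battered
 and 
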