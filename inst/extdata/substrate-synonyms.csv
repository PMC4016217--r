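pattern,canonical
cattail,cattail-marsh
cattails,cattail-marsh
cattail marsh,cattail-marsh
cattail-marsh,cattail-marsh
typha,cattail-marsh
marsh,cattail-marsh
bulrush,bulrush
bulrushes,bulrush
tule,bulrush
tules,bulrush
schoenoplectus,bulrush
blackberry,blackberry
blackberries,blackberry
himalayan blackberry,blackberry
rubus,blackberry
nettle,nettle
nettles,nettle
stinging nettle,nettle
stinging nettles,nettle
urtica,nettle
thistle,thistle
thistles,thistle
milk thistle,thistle
bull thistle,thistle
cirsium,thistle
silybum,thistle
triticale,grain-field
grain,grain-field
grains,grain-field
grain field,grain-field
grain fields,grain-field
grain-field,grain-field
silage,grain-field
wheat,grain-field
mustard,mustard
brassica,mustard
willow,willow
willows,willow
salix,willow
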