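format-version: 1.2
ontology: fixture

[Term]
id: FX:0000000
name: fixture root
namespace: fixture_process

[Term]
id: FX:0000001
name: branch one
namespace: fixture_process
is_a: FX:0000000 ! fixture root

[Term]
id: FX:0000002
name: branch two
namespace: fixture_process
is_a: FX:0000000

[Term]
id: FX:0000003
name: branch three
namespace: fixture_process
is_a: FX:0000000

[Term]
id: FX:0000004
name: branch four
namespace: fixture_process
is_a: FX:0000000

[Term]
id: FX:0000005
name: branch five
namespace: fixture_process
is_a: FX:0000000

[Term]
id: FX:0000006
name: branch six
namespace: fixture_process
is_a: FX:0000000

[Term]
id: FX:0000007
name: leaf seven
namespace: fixture_process
is_a: FX:0000001

[Term]
id: FX:0000008
name: leaf eight
namespace: fixture_process
is_a: FX:0000001

[Term]
id: FX:0000009
name: leaf nine
namespace: fixture_process
is_a: FX:0000002

[Term]
id: FX:0000010
name: leaf ten
namespace: fixture_process
is_a: FX:0000002

[Term]
id: FX:0000011
name: leaf eleven
namespace: fixture_process
is_a: FX:0000003

[Term]
id: FX:0000012
name: leaf twelve
namespace: fixture_process
is_a: FX:0000003

[Term]
id: FX:0000013
name: leaf thirteen
namespace: fixture_process
is_a: FX:0000004

[Term]
id: FX:0000014
name: diamond leaf fourteen
namespace: fixture_process
is_a: FX:0000004
is_a: FX:0000005

[Term]
id: FX:0000015
name: leaf fifteen
namespace: fixture_process
is_a: FX:0000005

[Term]
id: FX:0000016
name: leaf sixteen
namespace: fixture_process
is_a: FX:0000006
relationship: part_of FX:0000001 ! optional subsumption

[Term]
id: FX:0000017
name: leaf seventeen
namespace: fixture_process
is_a: FX:0000006

[Term]
id: FX:0000018
name: leaf eighteen
namespace: fixture_process
is_a: FX:0000001

[Term]
id: FX:0000019
name: leaf nineteen
namespace: fixture_process
is_a: FX:0000002

[Term]
id: FX:0000099
name: obsolete leaf
namespace: fixture_process
is_obsolete: true
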