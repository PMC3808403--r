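$MeshFormat
2.2 0 8
$EndMeshFormat
$PhysicalNames
3
2 1 "prox"
2 2 "dist"
2 3 "side"
$EndPhysicalNames
$Nodes
4
1 0 0 0
2 1 0 0
3 0 1 0
4 0 0 1
$EndNodes
$Elements
5
1 4 2 99 1 1 2 3 4
2 2 2 1 1 1 2 3
3 2 2 1 2 1 2 4
4 2 2 2 3 1 3 4
5 2 2 3 4 2 3 4
$EndElements
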