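# Space-group operators in triplet notation (International Tables settings).
# Covers space groups common for protein crystals; extend by adding blocks.
# A block starts with ">SYMBOL"; following lines are one operator each.
>P 1
x,y,z
>P 2
x,y,z
-x,y,-z
>P 21
x,y,z
-x,y+1/2,-z
>C 2
x,y,z
-x,y,-z
x+1/2,y+1/2,z
-x+1/2,y+1/2,-z
>P 2 2 2
x,y,z
-x,-y,z
-x,y,-z
x,-y,-z
>P 21 21 2
x,y,z
-x,-y,z
-x+1/2,y+1/2,-z
x+1/2,-y+1/2,-z
>P 21 21 21
x,y,z
-x+1/2,-y,z+1/2
-x,y+1/2,-z+1/2
x+1/2,-y+1/2,-z
>C 2 2 21
x,y,z
-x,-y,z+1/2
-x,y,-z+1/2
x,-y,-z
x+1/2,y+1/2,z
-x+1/2,-y+1/2,z+1/2
-x+1/2,y+1/2,-z+1/2
x+1/2,-y+1/2,-z
>P 41
x,y,z
-x,-y,z+1/2
-y,x,z+1/4
y,-x,z+3/4
>P 43
x,y,z
-x,-y,z+1/2
-y,x,z+3/4
y,-x,z+1/4
>P 41 21 2
x,y,z
-x,-y,z+1/2
-y+1/2,x+1/2,z+1/4
y+1/2,-x+1/2,z+3/4
-x+1/2,y+1/2,-z+1/4
x+1/2,-y+1/2,-z+3/4
y,x,-z
-y,-x,-z+1/2
>P 43 21 2
x,y,z
-x,-y,z+1/2
-y+1/2,x+1/2,z+3/4
y+1/2,-x+1/2,z+1/4
-x+1/2,y+1/2,-z+3/4
x+1/2,-y+1/2,-z+1/4
y,x,-z
-y,-x,-z+1/2
>P 31
x,y,z
-y,x-y,z+1/3
-x+y,-x,z+2/3
>P 32
x,y,z
-y,x-y,z+2/3
-x+y,-x,z+1/3
>P 3 2 1
x,y,z
-y,x-y,z
-x+y,-x,z
y,x,-z
x-y,-y,-z
-x,-x+y,-z
>P 61
x,y,z
x-y,x,z+1/6
-y,x-y,z+1/3
-x,-y,z+1/2
-x+y,-x,z+2/3
y,-x+y,z+5/6
>P 65
x,y,z
x-y,x,z+5/6
-y,x-y,z+2/3
-x,-y,z+1/2
-x+y,-x,z+1/3
y,-x+y,z+1/6
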