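{"level":1,"width":16,"height":8,"walls":[[0,0],[1,0],[2,0],[3,0],[4,0],[5,0],[6,0],[7,0],[8,0],[9,0],[10,0],[11,0],[12,0],[13,0],[14,0],[15,0],[0,1],[15,1],[0,2],[2,2],[3,2],[4,2],[5,2],[7,2],[8,2],[9,2],[10,2],[12,2],[13,2],[15,2],[0,3],[15,3],[0,4],[2,4],[3,4],[4,4],[5,4],[7,4],[8,4],[9,4],[10,4],[12,4],[13,4],[15,4],[0,5],[15,5],[0,6],[6,6],[11,6],[15,6],[0,7],[1,7],[2,7],[3,7],[4,7],[5,7],[6,7],[7,7],[8,7],[9,7],[10,7],[11,7],[12,7],[13,7],[14,7],[15,7]],"start":[1,1],"finish":[[13,6],[14,6]],"zones":{"1":[[5,1]],"2":[[10,1]],"3":[[7,3]],"4":[[3,5]]},"checkpoints":["2","4","F"]}
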