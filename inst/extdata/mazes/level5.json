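{"level":5,"width":22,"height":11,"walls":[[0,0],[1,0],[2,0],[3,0],[4,0],[5,0],[6,0],[7,0],[8,0],[9,0],[10,0],[11,0],[12,0],[13,0],[14,0],[15,0],[16,0],[17,0],[18,0],[19,0],[20,0],[21,0],[0,1],[7,1],[16,1],[21,1],[0,2],[2,2],[3,2],[4,2],[6,2],[7,2],[9,2],[10,2],[11,2],[12,2],[14,2],[16,2],[17,2],[19,2],[21,2],[0,3],[4,3],[6,3],[12,3],[14,3],[19,3],[21,3],[0,4],[2,4],[4,4],[6,4],[8,4],[9,4],[10,4],[12,4],[14,4],[15,4],[16,4],[17,4],[19,4],[21,4],[0,5],[2,5],[6,5],[12,5],[19,5],[21,5],[0,6],[2,6],[4,6],[5,6],[6,6],[8,6],[9,6],[11,6],[12,6],[13,6],[14,6],[15,6],[17,6],[18,6],[19,6],[21,6],[0,7],[2,7],[8,7],[15,7],[21,7],[0,8],[2,8],[3,8],[4,8],[6,8],[7,8],[8,8],[10,8],[11,8],[12,8],[13,8],[15,8],[17,8],[18,8],[19,8],[20,8],[21,8],[0,9],[14,9],[21,9],[0,10],[1,10],[2,10],[3,10],[4,10],[5,10],[6,10],[7,10],[8,10],[9,10],[10,10],[11,10],[12,10],[13,10],[14,10],[15,10],[16,10],[17,10],[18,10],[19,10],[20,10],[21,10]],"start":[1,1],"finish":[[18,9],[19,9]],"zones":{"1":[[3,1]],"2":[[12,1]],"3":[[19,1]],"4":[[10,3]],"5":[[4,5]],"6":[[9,5]],"7":[[17,5]],"8":[[6,7]],"9":[[11,7]]},"checkpoints":["9","6","F"]}
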